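# spinepattern

Reaction–diffusion simulation and morphometry of neuron dendritic spine
patterns.

Dendritic spines — the protrusions on dendrites that carry most
excitatory synapses — form four classical shapes (mushroom, stubby,
thin, branched), and both the shape mix and the density of spines along
a dendrite are disturbed in several nervous-system diseases.
`spinepattern` is for computational neuroscientists and modellers who
want a tested, scriptable implementation of the activator–inhibitor–
substrate account of how those patterns form, together with the
morphometric and linear-stability machinery needed to quantify the
results.

## The model

Four fields on a 2-D grid — activator $A$, inhibitor $H$, substrate $S$
and a bistable cytoskeleton marker $Y$ — evolve as

$$
\begin{aligned}
\partial_t A &= c A^2 S/H - \mu A + (\rho_A+\delta_A) Y + D_A \nabla^2 A \\
\partial_t H &= c A^2 S - \upsilon H + (\rho_H+\delta_H) Y + D_H \nabla^2 H \\
\partial_t S &= c_0 - \gamma S - \varepsilon Y S + D_S \nabla^2 S \\
\partial_t Y &= d A - e Y + Y^2/(1+fY^2)
\end{aligned}
$$

with $D_H \gg D_A$ (local activation, lateral inhibition).  The
substrate-consumption rate $\varepsilon$ stands for neuron activity and
controls spine *shape*; the exogenous source rates $\delta_A, \delta_H$
model externally supplied activator/inhibitor and control spine
*density*, through the Turing wavelength of the frozen
activator–inhibitor subsystem.

The package provides:

* a compiled explicit finite-difference integrator with zero-flux
  boundaries (`rd_simulate()`, `simulate_spine()`,
  `run_dendrite_protocol()`), bitwise deterministic;
* silhouette morphometry — height, head and neck widths, the RAW
  (relative average width) and RCW (relative constriction width) metrics
  and the branched/thin/stubby/mushroom classification flow chart
  (`measure_spine()`, `classify_spine()`), plus spine counting along a
  dendrite trunk (`spine_density()`);
* Turing-instability analysis of the frozen subsystem — steady states,
  Jacobians, dispersion relations $\lambda(k)$, instability rasters over
  the $(S, Y)$ plane and wavelengths $\Lambda = 2\pi/k_m$
  (`turing_space()`, `turing_wavelength()`, `analyze_point()`);
* scripted parameter sweeps reproducing the shape, density and
  wavelength experiments (`sweep_epsilon_shapes()`,
  `sweep_exogenous_density()`, `wavelength_vs_exogenous()`);
* pixel-exact synthetic spine silhouettes with ground-truth geometry for
  testing the morphometry (`synth_spine_mask()`), and a thin CLI
  (`inst/cli/spinepattern.R`).

## A worked example

Simulate one spine at a low consumption rate and classify it:

```r
library(spinepattern)

tr <- simulate_spine(epsilon = 0.02, delta_A = 0.01, delta_H = 5e-5)
measure_newborn_spine(tr)
#> spine_metrics: mushroom-type  h = 2.10  w_head = 2.10  w_neck = 1.50  RAW = 0.857  RCW = 0.286
```

A 7-row newborn bump whose head (2.1 length units) overhangs its 5-px
stalk (1.5 units): RAW ≥ 0.4 and RCW ≥ 0.25, hence mushroom-type.  At
`epsilon = 0.05` the same protocol yields a tall narrow column (RAW
0.27 < 0.4: thin-type), and at `epsilon = 0.9` a frozen two-armed shape
(branched).  Scanning `epsilon` reproduces the class intervals:

```r
scan <- sweep_epsilon_shapes(c(seq(0.01, 0.09, 0.01), seq(0.1, 0.9, 0.05)))
scan[scan$epsilon %in% c(0.02, 0.03, 0.05, 0.7, 0.75), c("epsilon", "raw", "rcw", "shape_class")]
#>    epsilon   raw   rcw shape_class
#> 2     0.02 0.857 0.286    mushroom
#> 3     0.03 0.545 0.182      stubby
#> 5     0.05 0.273 0.091        thin
#> 22    0.70 0.074 0.059        thin
#> 23    0.75    NA    NA    branched
```

The Turing analysis connects exogenous substances to spine density: at a
point of the instability band,

```r
p <- rd_preset("dendrite_spines")
turing_wavelength(0.45, 0.37, p)$wavelength
#> [1] 7.91138
```

and across dendrite simulations the wavelength falls with `delta_A`
(9.4 → 7.7 → 7.0 over 0, 0.01, 0.02) while measured spine counts rise
(4 → 12 → 20), the package's quantitative version of
"exogenous activator → shorter wavelength → denser spines".

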