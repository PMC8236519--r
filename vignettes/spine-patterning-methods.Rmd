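---
title: "Modelling dendritic spine patterning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dendritic spine patterning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinepattern)
```

## The model

Dendritic spines — the micron-scale protrusions on neuron dendrites that
carry most excitatory synapses — come in four classical shapes (mushroom,
stubby, thin, branched), and both their shape distribution and their
density along the dendrite change in disease.  `spinepattern` simulates
their formation with a four-field reaction–diffusion model of the
Gierer–Meinhardt activator–inhibitor–substrate family, extended with
exogenous source terms:

$$
\begin{aligned}
\partial_t A &= c\,A^2 S/H - \mu A + (\rho_A + \delta_A)\,Y + D_A \nabla^2 A\\
\partial_t H &= c\,A^2 S - \upsilon H + (\rho_H + \delta_H)\,Y + D_H \nabla^2 H\\
\partial_t S &= c_0 - \gamma S - \varepsilon Y S + D_S \nabla^2 S\\
\partial_t Y &= d\,A - e\,Y + \frac{Y^2}{1 + f Y^2}
\end{aligned}
$$

$A$ is a self-catalysing activator, $H$ a faster-diffusing inhibitor
($D_H \gg D_A$ gives local activation with lateral inhibition), $S$ a
consumable substrate whose depletion steers growth, and $Y$ a bistable
cytoskeleton marker whose high state ($Y \approx 0.89$) marks cell
territory; $Y \ge 0.5$ defines the silhouette.  The two quantities under
study are $\varepsilon$, the rate at which the cytoskeleton consumes
substrate (a proxy for neuron activity), and the exogenous source rates
$\delta_A$, $\delta_H$ that model externally supplied activator/inhibitor.
All quantities are dimensionless.  The parameter presets
(`rd_preset("spine")`, `"dendrite_trunk"`, `"dendrite_spines"`) carry the
coefficient sets of the three simulation protocols.

## Numerics

The equations are integrated with explicit forward Euler on a regular
grid (`dx = 0.3`) with a 5-point Laplacian divided by `dx^2` and
zero-flux (mirror) boundaries — the standard closed-domain assumption in
morphogenesis models.  The time step must satisfy
$dt < dx^2/(4\max D) \approx 0.0865$; the default `dt = 0.05` leaves a
comfortable margin, and halving it changes a fully formed spine's $Y$
field by about $10^{-3}$ in max-norm (checked in the test suite).
Numerical safeguards, all visible in the API:

* the inhibitor is clamped to `h_floor = 1e-6` inside the
  activator-equation denominator only (the background starts at
  $H = 10^{-3}$ and raw division is fragile);
* values that undershoot zero are clamped to zero after each step and
  counted; under all protocol conditions the clamp counter stays at zero;
* runs are bitwise deterministic; the optional symmetry-breaking noise
  (`noise_amp`) is drawn from a seeded RNG.  The default is no noise —
  the asymmetric seed already breaks symmetry.

The stepping kernel is written in C++ (Rcpp); a 16,000-step single-spine
run takes a few seconds.

## Initial states and protocols

The initial condition is a small rectangle of "neuron" values
($A = 2$, $H = 0.02$, $S = 1$, $Y = 1$) in an environment of
($A = 0.001$, $H = 0.001$, $S = 1$, $Y = 0$).  The seed is read as a
5-cell-wide, 10-cell-tall column flush with the bottom boundary.  This
orientation is a deliberate choice: a wide, flat pad (10 wide by 5 tall)
against a mirror boundary is provably stationary under the model — the
activator maximum sits at the pad's base, the level just above the pad
stays far below the cytoskeleton nucleation threshold
($A \gtrsim 0.73$ given $d$, $e$, $f$), and nothing ever grows.  The
tall, narrow column concentrates activator at its tip (the inhibitor
escapes laterally), nucleates new cytoskeleton above, and produces the
upward outgrowth the protocols rely on.

**Single spine.** On a $100 \times 100$ grid the spine grows upward from
the seed; the *newborn part* — everything above the seed's top row,
restricted to the connected component containing the seed — is measured
and classified.  The default duration is $t_{end} = 800$ (16,000 steps).
This is a calibrated quantity: the model produces the right shape
*sequence* at any moderate duration (slow fat growth at small
$\varepsilon$, fast thin growth at intermediate values, early frozen
branching at large values), but the paper-reported class *intervals* —
mushroom up to $\varepsilon = 0.02$, stubby to $0.04$, thin to $0.7$,
branched above — pin down the snapshot time.  Between $t \approx 600$ and
$1200$ the thin/branched boundary sits exactly between $\varepsilon=0.70$
and $0.75$; $t_{end} = 800$ also places the mushroom/stubby and
stubby/thin boundaries at the reported positions (within one scan step).
Much longer runs are qualitatively wrong for this purpose: every
moderate-$\varepsilon$ spine eventually sprouts lateral branches, and at
very long times the far background itself slowly erupts (the white-region
inhibitor decays until autocatalysis ignites), so the reported
morphologies are genuinely transient snapshots, as they are in the
developing tissue.

**Dendrite.** On a $150 \times 200$ grid, stage 1 grows a trunk from the
same seed under the trunk preset (no exogenous terms, $\varepsilon =
0.017$); the default 800,000 steps ($t = 40{,}000$) let the trunk span
about 160 rows.  (The trunk advances at only ~2.5 rows per 1000 time
units, so short stage-1 runs would leave nothing to decorate with
spines.)  Because stage 1 has no exogenous terms, one trunk is shared by
every condition of a sweep.  Stage 2 continues from the trunk under the
spine preset ($c_0 = 0.05$, $\varepsilon = 1$, $\delta$'s under study)
for $t = 750$ (15,000 steps), long enough for lateral spines to grow out
and separate, short enough that neighbouring canopies have not yet merged
into the space-filling network that develops at late times.

## Morphometry

Spine geometry is measured on the binary silhouette by row widths:

* $h$ — rows from the base to the tip, times `dx`;
* $w_{head}$ — maximum width over the distal half of the newborn rows
  (configurable `head_fraction`), ties broken distally;
* $w_{neck}$ — minimum width over all occupied rows strictly below the
  head row.  The neck search deliberately extends *below* the newborn
  base row into the stalk the spine grew from: a mushroom head that
  overhangs its stalk has its narrowest cross-section in previously
  existing tissue, and restricting the neck to newborn rows makes a
  positive constriction (RCW) unobtainable for any shape this model
  produces — the growing tip is always the narrowest newborn part.

From these, RAW $= (w_{head} + w_{neck})/(2h)$ measures overall
thickness and RCW $= (w_{head} - w_{neck})/h$ the head-over-neck
constriction (negative when the base is wider).  Classification follows
the flow chart: branched if the silhouette has two runs of $\ge 2$ px
separated by $\ge 2$ px persisting $\ge 3$ rows; else thin if
RAW $< 0.4$; else stubby if RCW $< 0.25$; else mushroom.  For a branched
spine the head width is not meaningful and no metrics are reported.

Spine counting along a dendrite removes a trunk band — the stage-1 trunk
columns plus a 5-px margin that also covers the thin parallel filaments
which develop alongside the trunk during stage 2 — and counts 4-connected
components of $\ge 4$ px within 25 px of the band, up to the trunk's top
row.  The window and row cap count spines at their roots: distal canopies
merge and long spines run along the domain walls, and counting those
regions measures the artefacts, not the density.  Arms formed by the
growing trunk tip splitting are trunk growth, not spines, and are
excluded by the row cap.

## Turing analysis

Freezing $S$ and $Y$ decouples an activator–inhibitor subsystem whose
steady state $(A^*, H^*)$ is found by substituting
$H^* = (cA^2S + (\rho_H + \delta_H)Y)/\upsilon$ and bisecting the
resulting scalar equation on $(0, 100]$ (80 bisection iterations;
residuals $< 10^{-10}$; when several roots exist the diffusion-free
stable one is preferred).  The dispersion relation
$\lambda(k)$ is the larger root of the characteristic quadratic of the
linearization with $-k^2 D$ on the diagonal; a point is Turing-unstable
when the steady state is stable without diffusion but
$\max_k \mathrm{Re}\,\lambda(k) > 0$, tested both by the classic
inequality $D_H f_A + D_A g_H > 2\sqrt{D_A D_H \det J}$ and by the sign
of the dispersion curve (the suite verifies the two agree).  The
wavelength is $\Lambda = 2\pi/k_m$ with $k_m$ located on a log-spaced
2000-point grid on $[0.01, 10]$ and refined by golden-section search; the
upper bound matches the shortest wavelength ($\approx 2\,dx$) the lattice
can express.

For trajectory analysis, the $(S, Y)$ curve of a probe cell is read from
the recorded snapshots and intersected with the instability region.  Two
practical points, both visible in the defaults:

* the instability region under the dendrite presets is a narrow diagonal
  band (roughly $S \in [0.35, 0.75]$, $Y \in [0.25, 0.55]$) and the
  cytoskeleton switch traverses it *fast* — faster than any reasonable
  snapshot interval — so `analyze_point()` intersects the densified
  polyline (20 interpolated points per segment) rather than the raw
  snapshots;
* cells already inside the trunk sit at $Y \approx 0.9$ for the whole of
  stage 2 and never cross the band, so the probe is taken in the column
  two cells outside the trunk silhouette, where spines nucleate.  The
  default probe search walks that column from the bottom and analyses the
  first cell whose cytoskeleton actually switches and whose curve
  intersects the space; the row used is reported.  The representative
  intersection is defined deterministically as the *last* curve point
  inside the space.

With the shared trunk, the wavelengths come out strictly ordered:
$\Lambda$ falls with $\delta_A$ (9.4 → 7.7 → 7.0 length units over
$\delta_A = 0, 0.01, 0.02$) and rises with $\delta_H$ (6.7 → 7.7 → 8.6
over $\delta_H = 0, 5\times10^{-5}, 10^{-4}$).  These are 23–31 grid
cells — the same scale as the observed ~28-row spacing of simulated
spines — which is the mechanism linking the exogenous terms to density:
more exogenous activator, shorter wavelength, denser spines; more
exogenous inhibitor, longer wavelength, sparser spines.

## What the sweeps show, and their limits

* **Shape scan** (`sweep_epsilon_shapes`): classes along
  $\varepsilon$ run mushroom (≤ 0.02) → stubby (0.03) → thin (≤ 0.70) →
  branched (≥ 0.75), with RAW falling monotonically.  The
  stubby/thin boundary lands at 0.03 rather than the reported 0.04 — one
  scan step — and the very smallest spine ($\varepsilon = 0.01$, four
  newborn rows) classifies stubby rather than mushroom because at that
  size the "distal half" is a two-row tip taper.  Sub-pixel spines are at
  the resolution limit of any silhouette operator.
* **Density sweeps** (`sweep_exogenous_density`): counts rise steeply
  with $\delta_A$ (4 → 20 over $0 \ldots 0.04$) but saturate once the
  trunk is packed at the minimum spacing, and fall steeply with
  $\delta_H$ (16 → 0) but hit zero before the largest levels — so strict
  monotonicity over all five levels holds in direction and in the
  endpoints, not at every intermediate step.  Counts under
  $\varepsilon \in [0.5, 2.5]$ vary by a few (thick low-$\varepsilon$
  spines merge at their bases; high-$\varepsilon$ ones branch), with
  equal counts at $\varepsilon = 2$ and $2.5$.
* **Wavelength sweep** (`wavelength_vs_exogenous`): strictly monotone as
  above, opposite in sign to the density changes.

## What the synthetic fixtures do and do not test

`synth_spine_mask()` draws pixel-exact mushroom/stubby/thin/branched
silhouettes with known geometry so the measurement operators are tested
against ground truth without simulation.  They emulate clean binary
shapes with a declared base row — not real Golgi-stained microscopy
(noise, anti-aliasing, curved dendrites, overlapping spines), so passing
morphometry tests demonstrates operator correctness, not readiness for
raw images.  Likewise the simulations are 2-D: heights and widths are
in-plane projections, and no claim is made about 3-D spine volumes.

## Problem sizes

The defaults used throughout the package (and its tests) are the protocol
sizes: $100\times100$ grids with 16,000 steps for single spines,
$150\times200$ with 800,000 + 15,000 steps for dendrites, a shared
stage-1 trunk per sweep, 200-point default instability rasters, and
2000-point dispersion grids.  The structural unit tests additionally use
miniature grids where only plumbing, not behaviour, is under test.
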