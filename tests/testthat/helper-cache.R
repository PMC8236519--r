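# Shared expensive simulation products, computed once per test session.
sim_cache <- new.env(parent = emptyenv())

cached_trunk <- function() {
  if (is.null(sim_cache$trunk)) {
    sim_cache$trunk <- compute_trunk()
  }
  sim_cache$trunk
}

# full epsilon shape scan used by several acceptance checks
cached_shape_scan <- function() {
  if (is.null(sim_cache$shape_scan)) {
    sim_cache$shape_scan <- sweep_epsilon_shapes(
      c(seq(0.01, 0.09, by = 0.01), seq(0.10, 0.90, by = 0.05)))
  }
  sim_cache$shape_scan
}

cached_spine_class <- function(epsilon, delta_A = 0.01, delta_H = 0.00005) {
  key <- paste0("cls_", epsilon, "_", delta_A, "_", delta_H)
  if (is.null(sim_cache[[key]])) {
    tr <- simulate_spine(epsilon = epsilon, delta_A = delta_A,
                         delta_H = delta_H)
    sim_cache[[key]] <- tryCatch(measure_newborn_spine(tr)$shape_class,
                                 error = function(e) "none")
  }
  sim_cache[[key]]
}
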