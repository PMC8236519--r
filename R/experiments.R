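#' Sweep the substrate consumption rate and classify spine shapes
#'
#' Runs the single-spine protocol once per \eqn{\varepsilon} value under a
#' shared schedule and classifies each newborn spine.  Reproduces the
#' shape experiment: with increasing consumption rate the spine passes
#' through mushroom, stubby, thin and branched forms while RAW and RCW
#' decrease.
#'
#' @param eps_values vector of \eqn{\varepsilon} values in \eqn{(0, 1]}.
#' @param delta_A,delta_H exogenous levels held fixed across the sweep
#'   (defaults: the standard levels 0.01 and 5e-5).
#' @param t_end,dt schedule shared by every run.
#' @param grid simulation grid.
#' @return A data.frame (class \code{"sweep_table"}) with one row per
#'   \eqn{\varepsilon}, columns \code{epsilon}, \code{h}, \code{w_head},
#'   \code{w_neck}, \code{raw}, \code{rcw}, \code{branched},
#'   \code{shape_class} and \code{ok} (FALSE for rows whose simulation or
#'   measurement failed); provenance in attributes.
#' @export
sweep_epsilon_shapes <- function(eps_values, delta_A = 0.01,
                                 delta_H = 0.00005, t_end = 800,
                                 dt = 0.05, grid = rd_grid(100, 100)) {
  stopifnot(all(eps_values > 0), all(eps_values <= 1))
  eps_values <- sort(eps_values)
  rows <- lapply(eps_values, function(eps) {
    tryCatch({
      tr <- simulate_spine(epsilon = eps, delta_A = delta_A,
                           delta_H = delta_H, t_end = t_end, dt = dt,
                           grid = grid)
      sm <- measure_newborn_spine(tr)
      data.frame(epsilon = eps, h = sm$h, w_head = sm$w_head,
                 w_neck = sm$w_neck, raw = sm$raw, rcw = sm$rcw,
                 branched = sm$branched, shape_class = sm$shape_class,
                 ok = TRUE, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(epsilon = eps, h = NA_real_, w_head = NA_real_,
                 w_neck = NA_real_, raw = NA_real_, rcw = NA_real_,
                 branched = NA, shape_class = NA_character_, ok = FALSE,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(delta_A = delta_A, delta_H = delta_H,
                                  t_end = t_end, dt = dt, grid = grid)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Stage-1 dendrite trunk
#'
#' Computes (or returns a cached copy of) the stage-1 trunk state.  The
#' trunk stage carries no exogenous terms, so a single trunk serves every
#' condition of a density sweep.
#'
#' @param grid dendrite grid.
#' @param schedule stage-1 schedule (default: the calibrated 800,000-step
#'   trunk outgrowth).
#' @return The stage-1 final [rd_state()].
#' @export
compute_trunk <- function(grid = rd_grid(150, 200),
                          schedule = rd_schedule(n_steps = 800000L)) {
  tr <- rd_simulate(make_initial_dendrite(grid),
                    rd_preset("dendrite_trunk"), grid, schedule)
  final_state(tr)
}

#' Sweep exogenous levels and measure dendrite spine density
#'
#' Runs the two-stage dendrite protocol once per condition (sharing the
#' stage-1 trunk) and counts spines along the trunk.  Conditions are
#' formed by recycling \code{delta_A}, \code{delta_H} and \code{epsilon}
#' to a common length, ordered by the swept (longest) argument.
#'
#' @param delta_A,delta_H,epsilon condition vectors (recycled).
#' @param t_end,dt stage-2 schedule shared by all conditions.
#' @param grid dendrite grid.
#' @param trunk optional precomputed stage-1 state from [compute_trunk()].
#' @param schedule1 stage-1 schedule used when \code{trunk} is NULL.
#' @return A \code{"sweep_table"} data.frame with columns \code{delta_A},
#'   \code{delta_H}, \code{epsilon}, \code{spine_count},
#'   \code{trunk_length}, \code{density}, \code{ok}.
#' @export
sweep_exogenous_density <- function(delta_A = 0.01, delta_H = 0.00005,
                                    epsilon = 1, t_end = 750, dt = 0.05,
                                    grid = rd_grid(150, 200),
                                    trunk = NULL,
                                    schedule1 = rd_schedule(n_steps = 800000L)) {
  n <- max(length(delta_A), length(delta_H), length(epsilon))
  conds <- data.frame(delta_A = rep_len(delta_A, n),
                      delta_H = rep_len(delta_H, n),
                      epsilon = rep_len(epsilon, n))
  if (is.null(trunk)) trunk <- compute_trunk(grid, schedule1)
  sched2 <- rd_schedule(dt = dt, n_steps = round(t_end / dt))
  rows <- lapply(seq_len(n), function(i) {
    cond <- conds[i, ]
    tryCatch({
      p2 <- rd_preset("dendrite_spines", delta_A = cond$delta_A,
                      delta_H = cond$delta_H, epsilon = cond$epsilon)
      tr <- run_dendrite_protocol(stage2 = p2, grid = grid,
                                  schedule2 = sched2,
                                  stage1_state = trunk)
      dr <- dendrite_density(tr)
      cbind(cond, data.frame(spine_count = dr$spine_count,
                             trunk_length = dr$trunk_length,
                             density = dr$density, ok = TRUE))
    }, error = function(e) {
      cbind(cond, data.frame(spine_count = NA_integer_,
                             trunk_length = NA_real_, density = NA_real_,
                             ok = FALSE))
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(t_end = t_end, dt = dt, grid = grid)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Sweep exogenous levels and compute the Turing wavelength
#'
#' Runs the dendrite protocol per condition with snapshot recording,
#' analyses the \eqn{(S, Y)} curve of a probe point on the trunk's central
#' axis ([analyze_point()]) and reports the Turing wavelength of the
#' representative intersection.  Reproduces the mechanism result: the
#' wavelength decreases with the exogenous activator and increases with
#' the exogenous inhibitor, and since the wavelength sets the spacing of
#' spines it is negatively related to their density.
#'
#' @inheritParams sweep_exogenous_density
#' @param record_every snapshot interval of the stage-2 run (steps).
#' @param probe_point optional \code{c(row, col)} used for every
#'   condition.  By default the probe is chosen per condition,
#'   deterministically: in the column two cells outside the trunk
#'   silhouette (the layer where spines nucleate; cells already inside
#'   the trunk sit at \eqn{Y \approx 0.9} throughout and never cross the
#'   instability space), the lowest row whose cytoskeleton actually
#'   switches during the run and whose \eqn{(S, Y)} curve intersects the
#'   instability space.  The row used is reported in the table.
#' @return A \code{"sweep_table"} data.frame with columns \code{delta_A},
#'   \code{delta_H}, \code{epsilon}, \code{S}, \code{Y},
#'   \code{lambda_m}, \code{k_m}, \code{wavelength}, \code{ok} (FALSE
#'   when there is no intersection).
#' @export
wavelength_vs_exogenous <- function(delta_A = 0.01, delta_H = 0.00005,
                                    epsilon = 1, t_end = 750, dt = 0.05,
                                    record_every = 1000L,
                                    grid = rd_grid(150, 200),
                                    trunk = NULL, probe_point = NULL,
                                    schedule1 = rd_schedule(n_steps = 800000L)) {
  n <- max(length(delta_A), length(delta_H), length(epsilon))
  conds <- data.frame(delta_A = rep_len(delta_A, n),
                      delta_H = rep_len(delta_H, n),
                      epsilon = rep_len(epsilon, n))
  if (is.null(trunk)) trunk <- compute_trunk(grid, schedule1)
  tm <- cell_mask(trunk$Y)
  trunk_top <- max(which(rowSums(tm) > 0))
  probe_col <- max(which(colSums(tm) > 0)) + 2L
  sched2 <- rd_schedule(dt = dt, n_steps = round(t_end / dt),
                        record_every = as.integer(record_every))
  rows <- lapply(seq_len(n), function(i) {
    cond <- conds[i, ]
    empty <- data.frame(probe_row = NA_integer_, S = NA_real_,
                        Y = NA_real_, lambda_m = NA_real_, k_m = NA_real_,
                        wavelength = NA_real_, ok = FALSE)
    tryCatch({
      p2 <- rd_preset("dendrite_spines", delta_A = cond$delta_A,
                      delta_H = cond$delta_H, epsilon = cond$epsilon)
      tr <- run_dendrite_protocol(stage2 = p2, grid = grid,
                                  schedule2 = sched2,
                                  stage1_state = trunk)
      if (is.null(probe_point)) {
        # lowest trunk-adjacent row whose cytoskeleton switches
        y_path <- sapply(tr$states, function(s) s$Y[seq_len(trunk_top),
                                                    probe_col])
        cand <- which(apply(y_path, 1, min) < 0.25 &
                      apply(y_path, 1, max) > 0.55)
      } else {
        cand <- probe_point[1]
      }
      res <- NULL
      used <- NA_integer_
      for (r in cand) {
        pt <- c(r, if (is.null(probe_point)) probe_col else probe_point[2])
        a <- analyze_point(tr, pt, params = p2)
        if (a$in_turing_space) { res <- a; used <- r; break }
      }
      if (is.null(res)) return(cbind(cond, empty))
      cbind(cond, data.frame(probe_row = used, S = res$S, Y = res$Y,
                             lambda_m = res$lambda_m, k_m = res$k_m,
                             wavelength = res$wavelength, ok = TRUE))
    }, error = function(e) cbind(cond, empty))
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(t_end = t_end, dt = dt, grid = grid,
                                  probe_point = probe_point)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' @export
print.sweep_table <- function(x, ...) {
  cat("sweep_table with", nrow(x), "conditions\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
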