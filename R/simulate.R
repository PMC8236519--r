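#' Reaction terms of the model
#'
#' Evaluates the four reaction right-hand sides (no diffusion) pointwise on
#' a state.  The inhibitor is clamped to \code{h_floor} inside the
#' activator-equation denominator before division.
#'
#' @param state an [rd_state()].
#' @param params an [rd_params()].
#' @param h_floor denominator guard for the inhibitor (default
#'   \code{1e-6}).
#' @return A list of four matrices \code{dA}, \code{dH}, \code{dS},
#'   \code{dY}.
#' @export
#' @examples
#' st <- uniform_state(c(A = 1, H = 1, S = 1, Y = 1), rd_grid(4, 4))
#' reaction_rhs(st, rd_preset("spine"))$dA[1, 1]  # = -0.138
reaction_rhs <- function(state, params, h_floor = 1e-6) {
  stopifnot(inherits(state, "rd_state"), inherits(params, "rd_params"))
  for (nm in c("A", "H", "S", "Y")) {
    if (any(!is.finite(state[[nm]]))) {
      stop("non-finite values in field ", nm)
    }
  }
  A <- state$A; H <- state$H; S <- state$S; Y <- state$Y
  p <- as.list(params)
  names(p) <- names(params)
  Hd <- pmax(H, h_floor)
  auto_cat <- p$c * A^2 * S
  list(
    dA = auto_cat / Hd - p$mu * A + (p$rho_A + p$delta_A) * Y,
    dH = auto_cat - p$nu * H + (p$rho_H + p$delta_H) * Y,
    dS = p$c0 - p$gamma * S - p$epsilon * Y * S,
    dY = p$d * A - p$e * Y + Y^2 / (1 + p$f * Y^2)
  )
}

#' Discrete Laplacian with zero-flux boundaries
#'
#' 5-point finite-difference Laplacian divided by \code{dx^2}, with mirror
#' (zero-flux) boundary conditions: out-of-domain neighbours are replaced
#' by the centre cell.  The operator conserves the field total exactly in
#' exact arithmetic.
#'
#' @param field a numeric matrix of shape \code{ny x nx}.
#' @param grid an [rd_grid()] matching the field shape.
#' @return A matrix of the same shape.
#' @export
rd_laplacian <- function(field, grid) {
  stopifnot(inherits(grid, "rd_grid"))
  if (!is.matrix(field) || nrow(field) != grid$ny || ncol(field) != grid$nx) {
    stop("field shape does not match grid")
  }
  nr <- nrow(field); nc <- ncol(field)
  up    <- field[c(1, seq_len(nr - 1)), , drop = FALSE]
  down  <- field[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  left  <- field[, c(1, seq_len(nc - 1)), drop = FALSE]
  right <- field[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  (up + down + left + right - 4 * field) / grid$dx^2
}

#' Advance the state by one explicit Euler step
#'
#' \code{new = old + dt * (reaction + diffusion)}, after which negative
#' values are clamped to zero.  The clamp count is returned as an
#' attribute.
#'
#' @param state an [rd_state()].
#' @param params an [rd_params()].
#' @param grid an [rd_grid()].
#' @param dt time step; must satisfy the stability bound of
#'   [rd_schedule()].
#' @param h_floor inhibitor denominator guard.
#' @return The advanced [rd_state()] with attribute \code{clamp_count}.
#' @export
rd_step <- function(state, params, grid, dt, h_floor = 1e-6) {
  stopifnot(inherits(state, "rd_state"))
  if (dt == 0) return(state)
  check_stability(rd_schedule(dt = dt, n_steps = 1L), params, grid)
  res <- rd_sim_cpp(state$A, state$H, state$S, state$Y,
                    as.numeric(params), grid$dx, dt,
                    1L, 1L, h_floor, check_every = 1L)
  sn <- res$snapshots[[1]]
  out <- rd_state(sn$A, sn$H, sn$S, sn$Y, t = state$t + dt)
  attr(out, "clamp_count") <- res$clamp_count
  out
}

#' Run a simulation
#'
#' Integrates the model from an initial state with explicit forward Euler,
#' recording snapshots every \code{record_every} steps (the initial state
#' and the final state are always part of the trajectory).  With
#' \code{noise_amp > 0} a uniform perturbation drawn with the schedule's
#' seed is added to the initial activator field, making runs reproducible
#' given the seed.  Runs are bitwise deterministic for identical inputs.
#'
#' @param state initial [rd_state()].
#' @param params an [rd_params()].
#' @param grid an [rd_grid()].
#' @param schedule an [rd_schedule()].
#' @param h_floor inhibitor denominator guard.
#' @return An object of class \code{"rd_trajectory"}: a list with
#'   \code{times}, \code{states} (list of [rd_state()]), \code{clamp_count}
#'   and the provenance (\code{params}, \code{grid}, \code{schedule}).
#' @export
rd_simulate <- function(state, params, grid, schedule, h_floor = 1e-6) {
  stopifnot(inherits(state, "rd_state"), inherits(schedule, "rd_schedule"))
  if (nrow(state$A) != grid$ny || ncol(state$A) != grid$nx) {
    stop("state shape does not match grid")
  }
  check_stability(schedule, params, grid)
  if (schedule$noise_amp > 0) {
    set.seed(schedule$seed)
    A <- state$A +
      matrix(stats::runif(length(state$A), -schedule$noise_amp,
                          schedule$noise_amp),
             nrow(state$A), ncol(state$A))
    state <- rd_state(pmax(A, 0), state$H, state$S, state$Y, t = state$t)
  }
  states <- list(state)
  times <- state$t
  clamps <- 0
  if (schedule$n_steps > 0) {
    res <- rd_sim_cpp(state$A, state$H, state$S, state$Y,
                      as.numeric(params), grid$dx, schedule$dt,
                      schedule$n_steps, schedule$record_every, h_floor)
    for (k in seq_along(res$snapshots)) {
      sn <- res$snapshots[[k]]
      t_k <- state$t + res$steps[k] * schedule$dt
      states[[k + 1]] <- rd_state(sn$A, sn$H, sn$S, sn$Y, t = t_k)
      times <- c(times, t_k)
    }
    clamps <- res$clamp_count
  }
  structure(list(times = times, states = states, clamp_count = clamps,
                 params = params, grid = grid, schedule = schedule),
            class = "rd_trajectory")
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat(sprintf(
    "rd_trajectory: %d snapshots, t in [%g, %g], %d x %d grid, %g clamps\n",
    length(x$times), min(x$times), max(x$times),
    x$grid$ny, x$grid$nx, x$clamp_count))
  invisible(x)
}

#' @export
#' @importFrom graphics image
plot.rd_trajectory <- function(x, field = "Y", snapshot = length(x$states),
                               ...) {
  st <- x$states[[snapshot]]
  M <- if (identical(field, "mask")) (st$Y >= 0.5) * 1 else st[[field]]
  image(t(M), useRaster = TRUE, axes = FALSE,
        main = sprintf("%s at t = %g", field, st$t), ...)
  invisible(x)
}

#' Final state of a trajectory
#' @param traj an \code{rd_trajectory}.
#' @return The last recorded [rd_state()].
#' @export
final_state <- function(traj) {
  stopifnot(inherits(traj, "rd_trajectory"))
  traj$states[[length(traj$states)]]
}

#' Two-stage dendrite protocol
#'
#' Stage 1 grows the dendrite trunk from the 5 x 10 seed under the trunk
#' parameter set; stage 2 continues from the stage-1 final state under the
#' spine-formation parameter set (with the exogenous levels under study).
#' The returned trajectory concatenates both stages and records the stage
#' boundary.
#'
#' @param stage1,stage2 [rd_params()] for the two stages; defaults are the
#'   \code{"dendrite_trunk"} and \code{"dendrite_spines"} presets.
#' @param grid an [rd_grid()]; default 150 x 200.
#' @param schedule1,schedule2 [rd_schedule()] for the two stages; defaults
#'   are the calibrated protocol schedules (see the package vignette).
#' @param stage1_state optionally, a precomputed stage-1 final
#'   [rd_state()]; stage 1 is then skipped.  Because stage 1 carries no
#'   exogenous terms it is identical across sweep conditions and is shared.
#' @param h_floor inhibitor denominator guard.
#' @return An \code{rd_trajectory} with extra elements
#'   \code{stage_boundary} (index of the last stage-1 snapshot) and
#'   \code{trunk} (the stage-1 final [rd_state()]).
#' @export
run_dendrite_protocol <- function(stage1 = rd_preset("dendrite_trunk"),
                                  stage2 = rd_preset("dendrite_spines"),
                                  grid = rd_grid(150, 200),
                                  schedule1 = rd_schedule(n_steps = 800000L),
                                  schedule2 = rd_schedule(n_steps = 30000L,
                                                          record_every = 1000L),
                                  stage1_state = NULL,
                                  h_floor = 1e-6) {
  if (is.null(stage1_state)) {
    tr1 <- rd_simulate(make_initial_dendrite(grid), stage1, grid, schedule1,
                       h_floor = h_floor)
  } else {
    tr1 <- structure(list(times = stage1_state$t, states = list(stage1_state),
                          clamp_count = 0, params = stage1, grid = grid,
                          schedule = schedule1),
                     class = "rd_trajectory")
  }
  trunk <- final_state(tr1)
  tr2 <- rd_simulate(trunk, stage2, grid, schedule2, h_floor = h_floor)
  out <- structure(list(
    times = c(tr1$times, tr2$times[-1]),
    states = c(tr1$states, tr2$states[-1]),
    clamp_count = tr1$clamp_count + tr2$clamp_count,
    params = stage2, grid = grid, schedule = schedule2,
    stage_boundary = length(tr1$states), trunk = trunk,
    stage1_params = stage1, stage1_schedule = schedule1),
    class = "rd_trajectory")
  out
}

#' Single-spine simulation at given exogenous and activity levels
#'
#' Convenience wrapper running the single-spine protocol: the 100 x 100
#' grid, the 5 x 10 seed and the calibrated default schedule
#' (\code{dt = 0.05}, 16000 steps, i.e. t_end = 800; see the vignette for
#' the calibration).
#'
#' @param epsilon substrate consumption rate.
#' @param delta_A,delta_H exogenous source rates.
#' @param t_end total simulated time.
#' @param dt time step.
#' @param grid an [rd_grid()].
#' @param record_every snapshot interval (steps); default records only the
#'   endpoints.
#' @return An \code{rd_trajectory}; its \code{seed_rows}/\code{seed_cols}
#'   elements carry the seed rectangle for morphometry.
#' @export
simulate_spine <- function(epsilon = 0.01, delta_A = 0.01,
                           delta_H = 0.00005, t_end = 800, dt = 0.05,
                           grid = rd_grid(100, 100), record_every = NULL) {
  params <- rd_preset("spine", epsilon = epsilon,
                      delta_A = delta_A, delta_H = delta_H)
  init <- make_initial_single_spine(grid)
  sched <- rd_schedule(dt = dt, n_steps = round(t_end / dt),
                       record_every = record_every)
  tr <- rd_simulate(init, params, grid, sched)
  tr$seed_rows <- attr(init, "seed_rows")
  tr$seed_cols <- attr(init, "seed_cols")
  tr
}
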