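#' Reaction-diffusion model parameters
#'
#' Builds the full coefficient set of the activator-inhibitor-substrate
#' model with exogenous source terms.  The four fields are the activator
#' \eqn{A}, the inhibitor \eqn{H}, the substrate \eqn{S} and the
#' cytoskeleton marker \eqn{Y}:
#' \deqn{\partial A/\partial t = c A^2 S / H - \mu A + (\rho_A+\delta_A) Y + D_A \nabla^2 A}
#' \deqn{\partial H/\partial t = c A^2 S - \upsilon H + (\rho_H+\delta_H) Y + D_H \nabla^2 H}
#' \deqn{\partial S/\partial t = c_0 - \gamma S - \varepsilon Y S + D_S \nabla^2 S}
#' \deqn{\partial Y/\partial t = d A - e Y + Y^2/(1 + f Y^2)}
#' All coefficients are dimensionless.  \code{delta_A} and \code{delta_H}
#' model externally supplied (exogenous) activator and inhibitor;
#' \code{epsilon} is the rate at which the cytoskeleton consumes substrate
#' and stands for neuron activity.
#'
#' @param c autocatalysis rate of the activator.
#' @param mu activator degradation rate \eqn{\mu}.
#' @param nu inhibitor degradation rate \eqn{\upsilon}.
#' @param rho_A endogenous activator source rate \eqn{\rho_A}.
#' @param rho_H endogenous inhibitor source rate \eqn{\rho_H}.
#' @param delta_A exogenous activator source rate \eqn{\delta_A}.
#' @param delta_H exogenous inhibitor source rate \eqn{\delta_H}.
#' @param c0 substrate production rate \eqn{c_0}.
#' @param gamma substrate degradation rate \eqn{\gamma}.
#' @param epsilon substrate consumption rate by the cytoskeleton
#'   \eqn{\varepsilon}.
#' @param D_A,D_H,D_S diffusion coefficients.  Lateral inhibition requires
#'   \code{D_H > D_A}; a warning is issued otherwise.
#' @param d cytoskeleton production rate from the activator.
#' @param e cytoskeleton degradation rate.
#' @param f saturation constant of the bistable cytoskeleton self-switch.
#'
#' @return An object of class \code{"rd_params"}: a named numeric vector of
#'   the 16 coefficients.
#' @seealso [rd_preset()] for the parameter sets used by the simulation
#'   protocols.
#' @export
#' @examples
#' p <- rd_params(rho_A = 0.01, delta_A = 0.01, epsilon = 0.05)
#' p["epsilon"]
rd_params <- function(c = 0.002, mu = 0.16, nu = 0.04,
                      rho_A = 0.01, rho_H = 0.00005,
                      delta_A = 0, delta_H = 0,
                      c0 = 0.02, gamma = 0.02, epsilon = 0.01,
                      D_A = 0.02, D_H = 0.26, D_S = 0.06,
                      d = 0.0035, e = 0.1, f = 10) {
  p <- c(c = c, mu = mu, nu = nu, rho_A = rho_A, rho_H = rho_H,
         delta_A = delta_A, delta_H = delta_H, c0 = c0, gamma = gamma,
         epsilon = epsilon, D_A = D_A, D_H = D_H, D_S = D_S,
         d = d, e = e, f = f)
  if (any(!is.finite(p))) {
    stop("all model parameters must be finite")
  }
  if (any(p < 0)) {
    stop("model parameters must be non-negative: ",
         paste(names(p)[p < 0], collapse = ", "))
  }
  if (D_H <= D_A) {
    warning("D_H <= D_A: no lateral inhibition, Turing patterning impossible")
  }
  structure(p, class = "rd_params")
}

#' Named parameter presets for the simulation protocols
#'
#' Returns the coefficient sets used by the three simulation protocols.
#' \describe{
#'   \item{\code{"spine"}}{single-spine protocol on a 100 x 100 grid
#'     (\eqn{\rho_A = 0.01}, \eqn{\rho_H = 5\times 10^{-5}},
#'     \eqn{c_0 = 0.02}); by default carries the standard exogenous levels
#'     \eqn{\delta_A = 0.01}, \eqn{\delta_H = 5\times 10^{-5}} of the
#'     shape experiments.}
#'   \item{\code{"dendrite_trunk"}}{first dendrite stage: trunk outgrowth
#'     (\eqn{\rho_A = 0.03}, \eqn{\rho_H = 10^{-4}},
#'     \eqn{\varepsilon = 0.017}, no exogenous terms).}
#'   \item{\code{"dendrite_spines"}}{second dendrite stage: spine formation
#'     along the trunk (\eqn{\rho_A = 0.02}, \eqn{\rho_H = 5\times 10^{-5}},
#'     \eqn{c_0 = 0.05}, \eqn{\varepsilon = 1} with the standard exogenous
#'     levels).}
#' }
#'
#' @param name preset name.
#' @param ... coefficient overrides passed on top of the preset, e.g.
#'   \code{epsilon = 0.05} or \code{delta_H = 1e-4}.
#' @return An [rd_params()] object.
#' @export
#' @examples
#' rd_preset("spine", epsilon = 0.03)
rd_preset <- function(name = c("spine", "dendrite_trunk", "dendrite_spines"),
                      ...) {
  name <- match.arg(name)
  base <- switch(name,
    spine = list(rho_A = 0.01, rho_H = 0.00005, c0 = 0.02,
                 delta_A = 0.01, delta_H = 0.00005, epsilon = 0.01),
    dendrite_trunk = list(rho_A = 0.03, rho_H = 0.0001, c0 = 0.02,
                          delta_A = 0, delta_H = 0, epsilon = 0.017),
    dendrite_spines = list(rho_A = 0.02, rho_H = 0.00005, c0 = 0.05,
                           delta_A = 0.01, delta_H = 0.00005, epsilon = 1)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(rd_params, base)
}

#' @export
print.rd_params <- function(x, ...) {
  cat("Reaction-diffusion parameters (16 coefficients)\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Simulation grid
#'
#' A regular 2-D grid with square cells and zero-flux (mirror) boundaries.
#' \code{nx} counts columns (horizontal direction), \code{ny} rows
#' (vertical direction); row 1 is the bottom of the domain, where the
#' growth protocols place their seed.
#'
#' @param nx,ny number of cells in x and y; at least 3.
#' @param dx cell spacing in model length units (default 0.3).
#' @return An object of class \code{"rd_grid"}.
#' @export
#' @examples
#' rd_grid()        # the 100 x 100 single-spine grid
#' rd_grid(150, 200)  # the dendrite grid
rd_grid <- function(nx = 100, ny = 100, dx = 0.3) {
  if (nx < 3 || ny < 3) stop("grid must be at least 3 x 3")
  if (!is.finite(dx) || dx <= 0) stop("dx must be positive")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx),
            class = "rd_grid")
}

#' @export
print.rd_grid <- function(x, ...) {
  cat(sprintf("rd_grid: %d x %d cells, dx = %g (%g x %g length units)\n",
              x$nx, x$ny, x$dx, x$nx * x$dx, x$ny * x$dx))
  invisible(x)
}

#' Integration schedule
#'
#' Time-stepping schedule for the explicit forward-Euler scheme.  The time
#' step must satisfy the diffusive stability bound
#' \eqn{dt < dx^2 / (4 \max(D_A, D_H, D_S))}; the constructor enforces the
#' bound when \code{params} and \code{grid} are supplied, and
#' [rd_simulate()] always enforces it.
#'
#' @param dt time step (default 0.05).
#' @param n_steps total number of steps (\eqn{\ge 0}).
#' @param record_every snapshot interval in steps; \code{NULL} records only
#'   the initial and final states.
#' @param noise_amp amplitude of an optional uniform symmetry-breaking
#'   perturbation added to the initial activator field (default 0, i.e.
#'   none: the asymmetric seed already breaks symmetry).
#' @param seed RNG seed used only when \code{noise_amp > 0}.
#' @param params,grid optional; when both are given the stability bound is
#'   checked at construction.
#' @return An object of class \code{"rd_schedule"}.
#' @export
#' @examples
#' rd_schedule(n_steps = 16000)
rd_schedule <- function(dt = 0.05, n_steps, record_every = NULL,
                        noise_amp = 0, seed = 1L,
                        params = NULL, grid = NULL) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (is.null(record_every)) record_every <- max(n_steps, 1L)
  if (record_every < 1) stop("record_every must be >= 1")
  s <- structure(list(dt = dt, n_steps = as.integer(n_steps),
                      record_every = as.integer(record_every),
                      noise_amp = noise_amp, seed = as.integer(seed)),
                 class = "rd_schedule")
  if (!is.null(params) && !is.null(grid)) {
    check_stability(s, params, grid)
  }
  s
}

check_stability <- function(schedule, params, grid) {
  dmax <- max(params[c("D_A", "D_H", "D_S")])
  bound <- grid$dx^2 / (4 * dmax)
  if (schedule$dt >= bound) {
    stop(sprintf(
      "dt = %g violates the explicit stability bound dx^2/(4 max D) = %g",
      schedule$dt, bound))
  }
  invisible(TRUE)
}

#' @export
print.rd_schedule <- function(x, ...) {
  cat(sprintf(
    "rd_schedule: dt = %g, n_steps = %d (t_end = %g), record_every = %d%s\n",
    x$dt, x$n_steps, x$dt * x$n_steps, x$record_every,
    if (x$noise_amp > 0)
      sprintf(", noise_amp = %g (seed %d)", x$noise_amp, x$seed) else ""))
  invisible(x)
}
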