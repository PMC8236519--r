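#' Steady state of the frozen activator-inhibitor subsystem
#'
#' With the substrate and cytoskeleton frozen at values \eqn{(S, Y)}, the
#' activator-inhibitor pair decouples into a two-species system.  Setting
#' its reaction terms to zero and substituting
#' \eqn{H^* = (c A^2 S + (\rho_H+\delta_H) Y)/\upsilon} into the activator
#' equation leaves a scalar root problem in \eqn{A}, solved by bracketed
#' bisection on \eqn{(0, 100]}.  When several roots exist the one that is
#' stable without diffusion (negative trace, positive determinant of the
#' Jacobian) is returned; otherwise the smallest positive root, flagged
#' unstable.
#'
#' @param S,Y frozen substrate and cytoskeleton values (non-negative).
#' @param params an [rd_params()].
#' @param a_max upper end of the root bracket.
#' @param n_scan number of scan points used for bracketing.
#' @return A list with \code{A}, \code{H}, \code{stable} (diffusion-free
#'   stability flag) and \code{exists}; when no positive root exists,
#'   \code{exists = FALSE} and the other entries are \code{NA}.
#' @export
#' @examples
#' # closed form at Y = 0: A* = nu/mu, H* = c S A*^2 / nu
#' ah_steady_state(1, 0, rd_preset("spine"))
ah_steady_state <- function(S, Y, params, a_max = 100, n_scan = 2000) {
  stopifnot(S >= 0, Y >= 0)
  p <- as.list(as.numeric(params)); names(p) <- names(params)
  src_A <- (p$rho_A + p$delta_A) * Y
  src_H <- (p$rho_H + p$delta_H) * Y
  h_of_a <- function(A) (p$c * A^2 * S + src_H) / p$nu
  g <- function(A) {
    H <- h_of_a(A)
    if (H <= 0) return(-p$mu * A + src_A)  # no inhibition at all
    p$c * A^2 * S / H - p$mu * A + src_A
  }
  a_grid <- exp(seq(log(1e-8), log(a_max), length.out = n_scan))
  gv <- vapply(a_grid, g, numeric(1))
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- numeric(0)
  for (i in flips) {
    lo <- a_grid[i]; hi <- a_grid[i + 1]
    for (iter in 1:80) {           # plain bisection: residuals to ~1e-14
      mid <- (lo + hi) / 2
      if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  exact <- a_grid[gv == 0]
  roots <- sort(unique(c(roots, exact)))
  roots <- roots[roots > 0]
  if (length(roots) == 0) {
    return(list(A = NA_real_, H = NA_real_, stable = NA, exists = FALSE))
  }
  stab <- vapply(roots, function(A) {
    J <- ah_jacobian(A, h_of_a(A), S, params)
    tr <- J$f_A + J$g_H
    det <- J$f_A * J$g_H - J$f_H * J$g_A
    tr < 0 && det > 0
  }, logical(1))
  pick <- if (any(stab)) which(stab)[1] else 1L
  list(A = roots[pick], H = h_of_a(roots[pick]), stable = stab[pick],
       exists = TRUE)
}

#' Jacobian of the frozen activator-inhibitor reaction terms
#'
#' Closed-form partial derivatives of the activator and inhibitor reaction
#' terms at a point \eqn{(A, H)} with frozen substrate \eqn{S}:
#' \eqn{f_A = 2cAS/H - \mu}, \eqn{f_H = -cA^2S/H^2}, \eqn{g_A = 2cAS},
#' \eqn{g_H = -\upsilon}.
#'
#' @param A,H activator and inhibitor values; \code{H > 0}.
#' @param S frozen substrate value.
#' @param params an [rd_params()].
#' @return An object of class \code{"ah_jacobian"}: list with
#'   \code{f_A}, \code{f_H}, \code{g_A}, \code{g_H} and the evaluation
#'   point.
#' @export
ah_jacobian <- function(A, H, S, params) {
  if (!is.finite(H) || H <= 0) stop("H must be positive")
  p <- as.list(as.numeric(params)); names(p) <- names(params)
  structure(list(
    f_A = 2 * p$c * A * S / H - p$mu,
    f_H = -p$c * A^2 * S / H^2,
    g_A = 2 * p$c * A * S,
    g_H = -p$nu,
    A = A, H = H, S = S), class = "ah_jacobian")
}

# largest-real-part eigenvalue of [[a, b], [c, d]] via the quadratic
# closed form; complex pairs compared by real part
lambda_max_2x2 <- function(a, b, c, d) {
  tr <- a + d
  disc <- tr * tr - 4 * (a * d - b * c)
  ifelse(disc >= 0, (tr + sqrt(pmax(disc, 0))) / 2, tr / 2)
}

#' Dispersion relation of the linearized system
#'
#' For each wavenumber \eqn{k}, the growth rate \eqn{\mathrm{Re}\,
#' \lambda(k)} is the largest-real-part eigenvalue of
#' \deqn{\begin{pmatrix} f_A - k^2 D_A & f_H \\ g_A & g_H - k^2 D_H
#' \end{pmatrix}}
#' computed from the closed-form quadratic root.  A spatially uniform
#' steady state is Turing-unstable when \eqn{\mathrm{Re}\,\lambda(0) < 0}
#' but \eqn{\mathrm{Re}\,\lambda(k) > 0} for some \eqn{k > 0}.
#'
#' @param jac an [ah_jacobian()].
#' @param D_A,D_H diffusion coefficients.
#' @param k wavenumber vector (non-negative, increasing).
#' @return An object of class \code{"dispersion_curve"}: a data.frame with
#'   columns \code{k} and \code{re_lambda}.
#' @export
dispersion_curve <- function(jac, D_A, D_H, k) {
  stopifnot(inherits(jac, "ah_jacobian"))
  re <- lambda_max_2x2(jac$f_A - k^2 * D_A, jac$f_H,
                       jac$g_A, jac$g_H - k^2 * D_H)
  structure(data.frame(k = k, re_lambda = re),
            class = c("dispersion_curve", "data.frame"))
}

#' @export
#' @importFrom graphics abline
plot.dispersion_curve <- function(x, ...) {
  plot(x$k, x$re_lambda, type = "l", xlab = "wavenumber k",
       ylab = expression(Re ~ lambda(k)), ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

turing_test_point <- function(S, Y, params, method) {
  ss <- ah_steady_state(S, Y, params)
  if (!ss$exists) {
    return(structure(FALSE, reason = "no steady state"))
  }
  J <- ah_jacobian(ss$A, ss$H, S, params)
  tr <- J$f_A + J$g_H
  det <- J$f_A * J$g_H - J$f_H * J$g_A
  if (!(tr < 0 && det > 0)) {
    return(structure(FALSE, reason = "unstable without diffusion"))
  }
  D_A <- params[["D_A"]]; D_H <- params[["D_H"]]
  ans <- if (method == "inequality") {
    D_H * J$f_A + D_A * J$g_H > 2 * sqrt(D_A * D_H * det)
  } else {
    k <- exp(seq(log(0.01), log(10), length.out = 2000))
    any(dispersion_curve(J, D_A, D_H, k)$re_lambda > 0)
  }
  structure(ans, reason = if (ans) NA_character_ else "diffusively stable",
            steady = ss, jacobian = J)
}

#' Test a frozen point for Turing instability
#'
#' A point of the \eqn{(S, Y)} plane is Turing-unstable when the frozen
#' activator-inhibitor subsystem has a steady state that is stable without
#' diffusion (negative trace, positive determinant) but is destabilized by
#' diffusion.  The default test uses the classic inequality
#' \eqn{D_H f_A + D_A g_H > 2\sqrt{D_A D_H \det J}}; the
#' \code{"dispersion"} method checks the sign of the dispersion curve on a
#' dense wavenumber grid.  The two agree (this is verified in the test
#' suite).
#'
#' @param S,Y frozen values.
#' @param params an [rd_params()].
#' @param method \code{"inequality"} (closed form) or \code{"dispersion"}.
#' @return Logical flag; when \code{FALSE} a \code{reason} attribute
#'   explains why (including the "no steady state" case).
#' @export
is_turing_unstable <- function(S, Y, params,
                               method = c("inequality", "dispersion")) {
  method <- match.arg(method)
  res <- turing_test_point(S, Y, params, method)
  out <- as.logical(res)
  attr(out, "reason") <- attr(res, "reason")
  out
}

#' Turing instability space over the S-Y plane
#'
#' Evaluates [is_turing_unstable()] on a regular raster of frozen
#' \eqn{(S, Y)} values.  The exogenous source terms enter the frozen
#' subsystem through \eqn{(\rho+\delta) Y}, so changing \eqn{\delta_A} or
#' \eqn{\delta_H} moves the instability region.
#'
#' @param params an [rd_params()].
#' @param S_range,Y_range ranges of the raster (default \code{c(0, 2)}).
#' @param resolution number of raster cells per axis (length 1 or 2).
#' @return An object of class \code{"turing_space"}: list with vectors
#'   \code{S}, \code{Y} and the logical matrix \code{unstable}
#'   (\code{length(Y)} rows by \code{length(S)} columns).
#' @export
turing_space <- function(params, S_range = c(0, 2), Y_range = c(0, 2),
                         resolution = 200) {
  stopifnot(all(S_range >= 0), all(Y_range >= 0))
  resolution <- rep(as.integer(resolution), length.out = 2)
  S_vals <- seq(S_range[1], S_range[2], length.out = resolution[1])
  Y_vals <- seq(Y_range[1], Y_range[2], length.out = resolution[2])
  unstable <- matrix(FALSE, length(Y_vals), length(S_vals))
  for (j in seq_along(S_vals)) {
    for (i in seq_along(Y_vals)) {
      unstable[i, j] <- is_turing_unstable(S_vals[j], Y_vals[i], params)
    }
  }
  structure(list(S = S_vals, Y = Y_vals, unstable = unstable,
                 params = params), class = "turing_space")
}

#' @export
print.turing_space <- function(x, ...) {
  cat(sprintf(
    "turing_space: %d x %d raster, %.1f%% unstable (S in [%g, %g], Y in [%g, %g])\n",
    length(x$Y), length(x$S), 100 * mean(x$unstable),
    min(x$S), max(x$S), min(x$Y), max(x$Y)))
  invisible(x)
}

#' @export
plot.turing_space <- function(x, ...) {
  image(x$S, x$Y, t(x$unstable) * 1, useRaster = TRUE,
        xlab = "S", ylab = "Y", main = "Turing instability space", ...)
  invisible(x)
}

#' Turing wavelength at a frozen point
#'
#' For a Turing-unstable point, locates the wavenumber \eqn{k_m}
#' maximizing \eqn{\mathrm{Re}\,\lambda(k)} over a log-spaced grid on
#' \eqn{[0.01, 10]} (2000 points) refined by golden-section search, and
#' returns \eqn{\lambda_m = \mathrm{Re}\,\lambda(k_m)} and the Turing
#' wavelength \eqn{\Lambda = 2\pi/k_m}.  The upper grid bound matches what
#' the simulation lattice can represent (wavelengths below about
#' \eqn{2 dx} are unphysical).
#'
#' @param S,Y frozen values.
#' @param params an [rd_params()].
#' @param k_range wavenumber bounds.
#' @param n_k grid size.
#' @return A list with \code{lambda_m}, \code{k_m}, \code{wavelength} and
#'   \code{unstable}; when the point is not Turing-unstable the numeric
#'   entries are \code{NA} and a \code{reason} is included.
#' @export
turing_wavelength <- function(S, Y, params, k_range = c(0.01, 10),
                              n_k = 2000) {
  flag <- is_turing_unstable(S, Y, params)
  if (!flag) {
    return(list(lambda_m = NA_real_, k_m = NA_real_,
                wavelength = NA_real_, unstable = FALSE,
                reason = attr(flag, "reason")))
  }
  ss <- ah_steady_state(S, Y, params)
  J <- ah_jacobian(ss$A, ss$H, S, params)
  D_A <- params[["D_A"]]; D_H <- params[["D_H"]]
  k <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n_k))
  re <- dispersion_curve(J, D_A, D_H, k)$re_lambda
  i <- which.max(re)
  lo <- k[max(1, i - 1)]; hi <- k[min(n_k, i + 1)]
  opt <- stats::optimize(function(kk)
    lambda_max_2x2(J$f_A - kk^2 * D_A, J$f_H, J$g_A, J$g_H - kk^2 * D_H),
    lower = lo, upper = hi, maximum = TRUE, tol = 1e-10)
  k_m <- opt$maximum
  list(lambda_m = opt$objective, k_m = k_m, wavelength = 2 * pi / k_m,
       unstable = TRUE)
}

#' S-Y curve of a trajectory at a grid point
#'
#' Reads the substrate and cytoskeleton values of one grid cell across all
#' recorded snapshots, in time order.  The curve is a pure readout of the
#' recorded trajectory: replaying it under different exogenous parameters
#' does not change it (only the instability space moves).
#'
#' @param traj an \code{rd_trajectory}.
#' @param point integer vector \code{c(row, col)} of the cell (row 1 =
#'   domain bottom).
#' @return A data.frame with columns \code{t}, \code{S}, \code{Y}.
#' @export
sy_trajectory <- function(traj, point) {
  stopifnot(inherits(traj, "rd_trajectory"), length(point) == 2)
  i <- as.integer(point[1]); j <- as.integer(point[2])
  st1 <- traj$states[[1]]
  if (i < 1 || i > nrow(st1$S) || j < 1 || j > ncol(st1$S)) {
    stop("point lies outside the grid")
  }
  data.frame(
    t = traj$times,
    S = vapply(traj$states, function(s) s$S[i, j], numeric(1)),
    Y = vapply(traj$states, function(s) s$Y[i, j], numeric(1)))
}

#' Turing analysis of a trajectory point
#'
#' Implements the instability analysis pipeline at one grid cell: extract
#' the \eqn{(S, Y)} curve of the cell, test every curve point for Turing
#' instability under the given parameters, select the representative
#' intersection of the curve with the instability space — deterministically
#' the \emph{last} curve point inside the space — and compute
#' \eqn{\lambda_m}, \eqn{k_m} and \eqn{\Lambda} there.
#'
#' @param traj an \code{rd_trajectory}.
#' @param point grid cell \code{c(row, col)}.
#' @param params parameters used for the instability test; defaults to the
#'   trajectory's own (pass others to re-analyze the same recorded curve
#'   under different exogenous levels).
#' @param n_interp number of linear interpolation points inserted per
#'   curve segment before intersecting with the instability space.  The
#'   cytoskeleton switch traverses the (narrow) instability band much
#'   faster than any practical snapshot interval, so the intersection is
#'   sought on the densified polyline (default 20).
#' @return An object of class \code{"turing_point_result"}: list with the
#'   representative \code{S}, \code{Y}, the steady state (\code{A_star},
#'   \code{H_star}), \code{jacobian}, \code{in_turing_space},
#'   \code{lambda_m}, \code{k_m}, \code{wavelength}, the full \code{curve}
#'   (with an \code{in_space} column) and \code{reason} when there is no
#'   intersection.
#' @export
analyze_point <- function(traj, point, params = traj$params,
                          n_interp = 20) {
  curve <- sy_trajectory(traj, point)
  # densified polyline through the recorded (t, S, Y) vertices
  if (nrow(curve) > 1 && n_interp > 0) {
    frac <- seq(0, 1, length.out = n_interp + 2)[-(n_interp + 2)]
    seg <- rep(seq_len(nrow(curve) - 1), each = n_interp + 1)
    w <- rep(frac, nrow(curve) - 1)
    dense <- data.frame(
      t = curve$t[seg] * (1 - w) + curve$t[seg + 1] * w,
      S = curve$S[seg] * (1 - w) + curve$S[seg + 1] * w,
      Y = curve$Y[seg] * (1 - w) + curve$Y[seg + 1] * w)
    dense <- rbind(dense, curve[nrow(curve), c("t", "S", "Y")])
  } else {
    dense <- curve
  }
  in_space <- vapply(seq_len(nrow(dense)), function(k)
    as.logical(is_turing_unstable(dense$S[k], dense$Y[k], params)),
    logical(1))
  curve$in_space <- curve$t %in% dense$t[in_space]
  if (!any(in_space)) {
    return(structure(list(
      S = NA_real_, Y = NA_real_, A_star = NA_real_, H_star = NA_real_,
      jacobian = NULL, in_turing_space = FALSE, lambda_m = NA_real_,
      k_m = NA_real_, wavelength = NA_real_, curve = curve,
      reason = "no intersection"), class = "turing_point_result"))
  }
  k <- max(which(in_space))
  S <- dense$S[k]; Y <- dense$Y[k]
  ss <- ah_steady_state(S, Y, params)
  tw <- turing_wavelength(S, Y, params)
  structure(list(
    S = S, Y = Y, A_star = ss$A, H_star = ss$H,
    jacobian = ah_jacobian(ss$A, ss$H, S, params),
    in_turing_space = TRUE, lambda_m = tw$lambda_m, k_m = tw$k_m,
    wavelength = tw$wavelength, curve = curve, reason = NA_character_),
    class = "turing_point_result")
}

#' @export
print.turing_point_result <- function(x, ...) {
  if (!x$in_turing_space) {
    cat("turing_point_result: no intersection with the instability space (",
        x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "turing_point_result: (S, Y) = (%.3f, %.3f)  lambda_m = %.4g  k_m = %.3f  wavelength = %.3f\n",
      x$S, x$Y, x$lambda_m, x$k_m, x$wavelength))
  }
  invisible(x)
}
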