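#' Parametric synthetic spine silhouettes
#'
#' Deterministic, pixel-exact rasterizations of the four spine families,
#' with ground-truth geometry recorded alongside the mask so that the
#' morphometry operators can be tested without running simulations.
#' Shapes are drawn horizontally centered above \code{base_row}:
#' \describe{
#'   \item{mushroom}{a disc-like head of maximum width \code{head_w_px}
#'     sitting on a neck column of width \code{neck_w_px}.}
#'   \item{stubby}{a short trapezoid whose base is at least as wide as
#'     its top (\code{neck_w_px} at the base tapering to
#'     \code{head_w_px}).}
#'   \item{thin}{a tall narrow column of width \code{neck_w_px} with a
#'     small cap of width \code{head_w_px}.}
#'   \item{branched}{a stem that splits into two diverging arms; the
#'     head width is not meaningful for this family.}
#' }
#' The recorded ground truth (\code{h_true}, \code{w_head_true},
#' \code{w_neck_true}) is computed from the generator's own row-width
#' sequence using the same conventions as [measure_spine()] (head = distal
#' maximum, neck = minimum below the head row), independently of the
#' raster.
#'
#' @param family one of \code{"mushroom"}, \code{"stubby"}, \code{"thin"},
#'   \code{"branched"}.
#' @param h_px spine height in pixels (at least 5).
#' @param head_w_px,neck_w_px head and neck widths in pixels (at least 1).
#' @param branch_angle lateral drift of each branched arm, in px per row
#'   (branched family only).
#' @param canvas \code{c(ny, nx)} raster size.
#' @param base_row rows at and below it are left empty (the mask contains
#'   only the spine).
#' @param dx physical spacing.
#' @param head_fraction distal fraction used when computing the
#'   ground-truth head (matches [measure_spine()]).
#' @return A [spine_mask()] with extra attributes \code{h_true},
#'   \code{w_head_true}, \code{w_neck_true}, \code{branched_true} and
#'   \code{family}.
#' @export
#' @examples
#' m <- synth_spine_mask("mushroom", h_px = 20, head_w_px = 12,
#'                       neck_w_px = 4)
#' measure_spine(m)
synth_spine_mask <- function(family = c("mushroom", "stubby", "thin",
                                        "branched"),
                             h_px, head_w_px = NULL, neck_w_px,
                             branch_angle = 1, canvas = NULL, base_row = 2,
                             dx = 0.3, head_fraction = 0.5) {
  family <- match.arg(family)
  if (h_px < 5) stop("h_px must be at least 5")
  if (neck_w_px < 1 || (!is.null(head_w_px) && head_w_px < 1)) {
    stop("widths must be at least 1 px")
  }
  if (family != "branched" && is.null(head_w_px)) {
    stop("head_w_px required for non-branched families")
  }

  widths <- switch(family,
    mushroom = {
      head_h <- max(3L, ceiling(head_w_px / 2))
      neck_h <- h_px - head_h
      if (neck_h < 1) stop("h_px too small for the head")
      taper <- pmax(head_w_px - 2 * abs(seq_len(head_h) -
                                          ceiling(head_h / 2)),
                    neck_w_px)
      c(rep(neck_w_px, neck_h), taper)
    },
    stubby = round(seq(neck_w_px, head_w_px, length.out = h_px)),
    thin = {
      cap_h <- max(2L, ceiling(head_w_px / 2))
      c(rep(neck_w_px, h_px - cap_h), rep(head_w_px, cap_h))
    },
    branched = NULL)

  if (is.null(canvas)) {
    w_need <- if (family == "branched") {
      2 * neck_w_px + 2 * ceiling(branch_angle * h_px) + 8
    } else {
      max(widths) + 4
    }
    canvas <- c(base_row + h_px + 2, w_need)
  }
  ny <- canvas[1]; nx <- canvas[2]
  if (base_row + h_px > ny) stop("silhouette does not fit the canvas")
  mask <- matrix(FALSE, ny, nx)
  centre <- (nx + 1) %/% 2

  row_span <- function(c0, w) {
    lo <- c0 - (w - 1L) %/% 2L
    hi <- lo + w - 1L
    if (lo < 1 || hi > nx) stop("silhouette does not fit the canvas")
    lo:hi
  }

  if (family == "branched") {
    stem_h <- max(3L, round(h_px / 3))
    for (r in seq_len(stem_h)) {
      mask[base_row + r, row_span(centre, 2L * neck_w_px)] <- TRUE
    }
    for (r in seq(stem_h + 1, h_px)) {
      off <- ceiling(branch_angle * (r - stem_h)) + neck_w_px
      mask[base_row + r, row_span(centre - off, neck_w_px)] <- TRUE
      mask[base_row + r, row_span(centre + off, neck_w_px)] <- TRUE
    }
    truth <- list(h_true = h_px * dx, w_head_true = NA_real_,
                  w_neck_true = NA_real_, branched_true = TRUE)
  } else {
    for (r in seq_len(h_px)) {
      mask[base_row + r, row_span(centre, widths[r])] <- TRUE
    }
    # ground truth from the width sequence, by the measurement conventions
    distal_from <- max(1L, h_px - ceiling(h_px * head_fraction) + 1L)
    w_head <- max(widths[distal_from:h_px])
    head_row <- distal_from - 1L +
      max(which(widths[distal_from:h_px] == w_head))
    w_neck <- if (head_row > 1) min(widths[seq_len(head_row - 1)])
              else w_head
    truth <- list(h_true = h_px * dx, w_head_true = w_head * dx,
                  w_neck_true = w_neck * dx, branched_true = FALSE)
  }
  out <- spine_mask(mask, base_row = base_row, dx = dx)
  attr(out, "truth") <- truth
  attr(out, "family") <- family
  out
}

#' Seeded random Jacobians with activator-inhibitor sign structure
#'
#' Reproducible random 2 x 2 Jacobians with \code{f_H < 0}, \code{g_A > 0}
#' and \code{g_H < 0} (the sign structure of the frozen
#' activator-inhibitor subsystem), for cross-checking the closed-form
#' dispersion relation against a numeric eigensolver.
#'
#' @param n number of Jacobians.
#' @param seed RNG seed.
#' @return A list of [ah_jacobian()]-classed objects.
#' @export
seeded_random_jacobians <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    structure(list(
      f_A = stats::runif(1, -1, 1),
      f_H = -stats::runif(1, 0.01, 2),
      g_A = stats::runif(1, 0.01, 2),
      g_H = -stats::runif(1, 0.01, 1),
      A = NA_real_, H = NA_real_, S = NA_real_), class = "ah_jacobian")
  })
}
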