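#' Field state container
#'
#' Holds the four scalar fields on an \code{ny x nx} grid (matrices in
#' row-major visual convention: row 1 is the bottom of the domain) plus the
#' current simulation time.
#'
#' @param A,H,S,Y numeric matrices of identical dimension, all finite and
#'   non-negative.
#' @param t simulation time of the state.
#' @return An object of class \code{"rd_state"}.
#' @export
rd_state <- function(A, H, S, Y, t = 0) {
  dims <- dim(A)
  for (nm in c("A", "H", "S", "Y")) {
    M <- get(nm)
    if (!is.matrix(M) || !identical(dim(M), dims)) {
      stop("field ", nm, " must be a matrix with the same shape as A")
    }
    if (any(!is.finite(M))) stop("non-finite values in field ", nm)
    if (any(M < 0)) stop("negative values in field ", nm)
  }
  structure(list(A = A, H = H, S = S, Y = Y, t = t), class = "rd_state")
}

#' @export
print.rd_state <- function(x, ...) {
  cat(sprintf("rd_state: %d x %d grid at t = %g\n",
              nrow(x$A), ncol(x$A), x$t))
  for (nm in c("A", "H", "S", "Y")) {
    M <- x[[nm]]
    cat(sprintf("  %s: range [%.4g, %.4g], mean %.4g\n",
                nm, min(M), max(M), mean(M)))
  }
  invisible(x)
}

#' Spatially uniform state
#'
#' @param values named list or vector with elements \code{A}, \code{H},
#'   \code{S}, \code{Y} (non-negative scalars).
#' @param grid an [rd_grid()].
#' @param t simulation time stamp.
#' @return An [rd_state()] with constant fields.
#' @export
#' @examples
#' uniform_state(c(A = 0.25, H = 0.003125, S = 1, Y = 0), rd_grid(5, 5))
uniform_state <- function(values, grid, t = 0) {
  values <- as.list(values)
  mk <- function(v) matrix(v, grid$ny, grid$nx)
  rd_state(mk(values$A), mk(values$H), mk(values$S), mk(values$Y), t = t)
}

# values inside the seed rectangle ("black region": a part of the neuron)
# and outside it ("white region": the surrounding environment)
seed_values  <- c(A = 2,     H = 0.02,  S = 1, Y = 1)
white_values <- c(A = 0.001, H = 0.001, S = 1, Y = 0)

make_seed_state <- function(grid, seed_w, seed_h) {
  if (seed_w > grid$nx || seed_h > grid$ny) {
    stop("seed rectangle does not fit the grid")
  }
  mk <- function(v) matrix(v, grid$ny, grid$nx)
  A <- mk(white_values["A"]); H <- mk(white_values["H"])
  S <- mk(white_values["S"]); Y <- mk(white_values["Y"])
  c0 <- (grid$nx - seed_w) %/% 2 + 1
  cols <- c0:(c0 + seed_w - 1)
  rows <- seq_len(seed_h)
  A[rows, cols] <- seed_values["A"]; H[rows, cols] <- seed_values["H"]
  S[rows, cols] <- seed_values["S"]; Y[rows, cols] <- seed_values["Y"]
  st <- rd_state(A, H, S, Y, t = 0)
  attr(st, "seed_cols") <- cols
  attr(st, "seed_rows") <- rows
  st
}

#' Initial state of the single-spine protocol
#'
#' A 5-cell-wide, 10-cell-tall seed rectangle flush with the bottom
#' boundary and horizontally centered, carrying the "black region" values
#' \eqn{A = 2}, \eqn{H = 0.02}, \eqn{S = 1}, \eqn{Y = 1}; elsewhere the
#' "white region" values \eqn{A = 0.001}, \eqn{H = 0.001}, \eqn{S = 1},
#' \eqn{Y = 0}.  The seed represents a part of the neuron from which the
#' spine grows upward.
#'
#' @param grid an [rd_grid()], by default the 100 x 100 spine grid.
#' @return An [rd_state()] with attributes \code{seed_cols} and
#'   \code{seed_rows} marking the seed rectangle.
#' @export
make_initial_single_spine <- function(grid = rd_grid(100, 100)) {
  make_seed_state(grid, seed_w = 5, seed_h = 10)
}

#' Initial state of the dendrite protocol
#'
#' The same 5 x 10 bottom-centered seed on the 150 x 200 dendrite grid
#' (150 columns wide, 200 rows tall); the dendrite trunk grows upward from
#' it during stage 1.
#'
#' @param grid an [rd_grid()], by default 150 x 200.
#' @return An [rd_state()] with seed attributes, as
#'   [make_initial_single_spine()].
#' @export
make_initial_dendrite <- function(grid = rd_grid(150, 200)) {
  make_seed_state(grid, seed_w = 5, seed_h = 10)
}

#' Write and read state checkpoints
#'
#' A checkpoint is a single RDS file holding the four rasters, the time
#' stamp and, when present, the provenance attributes.  Round-trips are
#' bit-exact.
#'
#' @param state an [rd_state()].
#' @param path file path.
#' @return \code{write_state} returns \code{path} invisibly;
#'   \code{read_state} returns the restored [rd_state()].
#' @export
write_state <- function(state, path) {
  stopifnot(inherits(state, "rd_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  st <- readRDS(path)
  if (!inherits(st, "rd_state")) stop("file does not contain an rd_state")
  st
}

#' Export a field or mask as a PNG image
#'
#' Writes a grayscale PNG of one field (scaled to its range) or of the
#' thresholded cell mask.  Row 1 of the state is rendered at the bottom of
#' the image.
#'
#' @param state an [rd_state()].
#' @param path output file path.
#' @param field one of \code{"A"}, \code{"H"}, \code{"S"}, \code{"Y"} or
#'   \code{"mask"} (the \code{Y >= threshold} silhouette).
#' @param threshold mask threshold used when \code{field = "mask"}.
#' @return \code{path}, invisibly.
#' @export
write_state_png <- function(state, path, field = "Y", threshold = 0.5) {
  stopifnot(inherits(state, "rd_state"))
  img <- if (identical(field, "mask")) {
    (state$Y >= threshold) * 1
  } else {
    M <- state[[field]]
    rng <- range(M)
    if (diff(rng) == 0) M * 0 else (M - rng[1]) / diff(rng)
  }
  # flip vertically: matrix row 1 (domain bottom) goes to the image bottom
  png::writePNG(img[rev(seq_len(nrow(img))), , drop = FALSE], path)
  invisible(path)
}

#' @rdname write_state_png
#' @export
write_state_tiff <- function(state, path, field = "Y", threshold = 0.5) {
  stopifnot(inherits(state, "rd_state"))
  img <- if (identical(field, "mask")) {
    (state$Y >= threshold) * 1
  } else {
    M <- state[[field]]
    rng <- range(M)
    if (diff(rng) == 0) M * 0 else (M - rng[1]) / diff(rng)
  }
  tiff::writeTIFF(img[rev(seq_len(nrow(img))), , drop = FALSE], path)
  invisible(path)
}
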