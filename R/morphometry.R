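#' Threshold the cytoskeleton field into a cell silhouette
#'
#' The cytoskeleton marker \code{Y} is bistable (its self-switch term makes
#' it settle near 0 outside the cell and near 0.89 inside), so the midpoint
#' threshold 0.5 is a robust silhouette cut.
#'
#' @param Y numeric matrix (finite).
#' @param threshold cut level, default 0.5.
#' @return A logical matrix, \code{TRUE} where \code{Y >= threshold}.
#' @export
cell_mask <- function(Y, threshold = 0.5) {
  if (any(!is.finite(Y))) stop("Y contains non-finite values")
  Y >= threshold
}

#' Spine mask container
#'
#' A boolean raster together with the row index that separates the newborn
#' spine from the original seed or trunk (\code{base_row}: rows above it
#' are the newborn part) and the physical cell spacing.
#'
#' @param mask logical matrix; row 1 is the bottom.
#' @param base_row last row of the original structure; 0 when the whole
#'   mask is the spine.
#' @param dx physical spacing (default 0.3).
#' @return An object of class \code{"spine_mask"}.
#' @export
spine_mask <- function(mask, base_row = 0, dx = 0.3) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (base_row < 0 || base_row >= nrow(mask)) {
    stop("base_row must lie inside the mask")
  }
  structure(list(mask = mask, base_row = as.integer(base_row), dx = dx),
            class = "spine_mask")
}

#' @export
print.spine_mask <- function(x, ...) {
  cat(sprintf("spine_mask: %d x %d px, base_row = %d, dx = %g, %d px set\n",
              nrow(x$mask), ncol(x$mask), x$base_row, x$dx, sum(x$mask)))
  invisible(x)
}

# 4-connected component containing any of the given cells (linear indices);
# returns a logical matrix.  Used to isolate the spine from detached blobs.
connected_component <- function(mask, seed_idx) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  queue <- seed_idx[mask[seed_idx]]
  seen[queue] <- TRUE
  head <- 1L
  queue <- as.integer(queue)
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    i <- (v - 1L) %% nr + 1L
    j <- (v - 1L) %/% nr + 1L
    nb <- c(if (i > 1L) v - 1L, if (i < nr) v + 1L,
            if (j > 1L) v - nr, if (j < nc) v + nr)
    nb <- nb[mask[nb] & !seen[nb]]
    if (length(nb)) {
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  seen
}

# label all 4-connected components; returns an integer matrix (0 = empty)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nlab <- 0L
  todo <- which(mask)
  for (v in todo) {
    if (lab[v] == 0L) {
      nlab <- nlab + 1L
      comp <- connected_component(mask, v)
      lab[comp] <- nlab
    }
  }
  lab
}

newborn_rows <- function(sm) {
  wp <- rowSums(sm$mask)
  above <- wp[seq(sm$base_row + 1, nrow(sm$mask))]
  top_rel <- suppressWarnings(max(which(above > 0)))
  if (!is.finite(top_rel)) stop("no spine cells above base_row")
  list(widths = above[seq_len(top_rel)], top = sm$base_row + top_rel,
       all_widths = wp)
}

#' Per-row width profile of the newborn spine
#'
#' For each row above \code{base_row} up to the spine tip, the width is the
#' count of set pixels in that row times \code{dx}.
#'
#' @param mask a [spine_mask()].
#' @return Numeric vector of widths (physical units), proximal to distal.
#' @export
width_profile <- function(mask) {
  stopifnot(inherits(mask, "spine_mask"))
  nb <- newborn_rows(mask)
  nb$widths * mask$dx
}

#' Measure spine height, head width and neck width
#'
#' The height \code{h} is the number of rows from \code{base_row + 1} to
#' the topmost occupied row, times \code{dx}.  The head width is the
#' maximum of the width profile over the distal part of the newborn rows
#' (the top \code{head_fraction} of them; ties broken toward the distal
#' end).  The neck is the narrowest cross-section between the structure's
#' base and the head row: the minimum row width over all occupied rows
#' strictly below the head row, \emph{including} rows at or below
#' \code{base_row} when the newborn head overhangs a pre-existing stalk —
#' the narrow section of a mushroom-like spine frequently lies in the
#' stalk it grew from.  For a spine with no occupied rows below its head
#' row the neck equals the head width.
#'
#' @param mask a [spine_mask()].
#' @param head_fraction distal fraction of the newborn rows searched for
#'   the head (default 0.5).
#' @return A list with \code{h}, \code{w_head}, \code{w_neck} (physical
#'   units).
#' @export
measure_spine <- function(mask, head_fraction = 0.5) {
  stopifnot(inherits(mask, "spine_mask"))
  nb <- newborn_rows(mask)
  wp <- nb$widths
  top <- length(wp)
  h <- top * mask$dx
  distal_from <- max(1L, top - ceiling(top * head_fraction) + 1L)
  distal <- wp[distal_from:top]
  w_head_px <- max(distal)
  head_row <- mask$base_row + distal_from - 1L +
    max(which(distal == w_head_px))
  below <- nb$all_widths[seq_len(head_row - 1)]
  below <- below[below > 0]
  w_neck_px <- if (length(below)) min(below) else w_head_px
  list(h = h, w_head = w_head_px * mask$dx, w_neck = w_neck_px * mask$dx)
}

#' Relative average width (RAW)
#'
#' \code{(w_head + w_neck) / (2 h)}: the overall thickness of a spine
#' relative to its height.  Small values indicate thin spines; 0.4 is the
#' default thin/non-thin criterion used by [classify_spine()].
#'
#' @param h,w_head,w_neck spine measurements (same units); \code{h > 0}.
#' @return A dimensionless scalar.
#' @export
#' @examples
#' raw_metric(2, 1, 0.5)  # 0.375
raw_metric <- function(h, w_head, w_neck) {
  if (!is.finite(h) || h <= 0) stop("h must be positive")
  (w_head + w_neck) / (2 * h)
}

#' Relative constriction width (RCW)
#'
#' \code{(w_head - w_neck) / h}: the head-over-neck constriction relative
#' to height.  It is small or even negative when the head is thinner or
#' barely thicker than the neck (stubby spines) and large for mushroom
#' spines; 0.25 is the default stubby/mushroom criterion.
#'
#' @inheritParams raw_metric
#' @return A dimensionless scalar (may be negative).
#' @export
#' @examples
#' rcw_metric(2, 1, 0.5)  # 0.25
rcw_metric <- function(h, w_head, w_neck) {
  if (!is.finite(h) || h <= 0) stop("h must be positive")
  (w_head - w_neck) / h
}

#' Detect a branching structure
#'
#' A spine is branched when some rows of its newborn part contain two or
#' more separate runs of set pixels — each run at least \code{min_run} px
#' wide, separated by at least \code{min_gap} px — and this multi-run
#' condition persists over at least \code{min_persist} consecutive rows.
#' The first two rows above the base are exempt (attachment roughness).
#'
#' @param mask a [spine_mask()].
#' @param min_run,min_gap,min_persist detection minima in pixels/rows
#'   (defaults 2/2/3).
#' @return Logical flag.
#' @export
is_branched <- function(mask, min_run = 2, min_gap = 2, min_persist = 3) {
  stopifnot(inherits(mask, "spine_mask"))
  nb <- newborn_rows(mask)
  top <- nb$top
  first <- mask$base_row + 3L   # rows above base_row + 2
  if (first > top) return(FALSE)
  rows <- seq(first, top)
  multi <- vapply(rows, function(i) {
    r <- rle(as.vector(mask$mask[i, ]))
    runs <- which(r$values & r$lengths >= min_run)
    if (length(runs) < 2) return(FALSE)
    for (a in seq_len(length(runs) - 1)) {
      gap_lens <- r$lengths[seq(runs[a] + 1, runs[a + 1] - 1)]
      gap <- sum(gap_lens[!r$values[seq(runs[a] + 1, runs[a + 1] - 1)]])
      if (gap >= min_gap) return(TRUE)
    }
    FALSE
  }, logical(1))
  rr <- rle(multi)
  any(rr$values & rr$lengths >= min_persist)
}

#' Classify a spine silhouette
#'
#' Decision flow: a branching structure is branched; otherwise a spine
#' with RAW below \code{raw_threshold} is thin; otherwise RCW below
#' \code{rcw_threshold} makes it stubby; otherwise it is mushroom.  For a
#' branched spine the head width is not meaningful and no metrics are
#' reported.
#'
#' @param mask a [spine_mask()].
#' @param raw_threshold thin/non-thin criterion (default 0.4).
#' @param rcw_threshold stubby/mushroom criterion (default 0.25).
#' @param head_fraction passed to [measure_spine()].
#' @return An object of class \code{"spine_metrics"}: list with \code{h},
#'   \code{w_head}, \code{w_neck}, \code{raw}, \code{rcw}, \code{branched}
#'   and \code{shape_class} (one of \code{"mushroom"}, \code{"stubby"},
#'   \code{"thin"}, \code{"branched"}).  For branched spines the metric
#'   fields are \code{NA}.
#' @export
classify_spine <- function(mask, raw_threshold = 0.4, rcw_threshold = 0.25,
                           head_fraction = 0.5) {
  stopifnot(inherits(mask, "spine_mask"))
  branched <- is_branched(mask)
  if (branched) {
    out <- list(h = NA_real_, w_head = NA_real_, w_neck = NA_real_,
                raw = NA_real_, rcw = NA_real_, branched = TRUE,
                shape_class = "branched")
  } else {
    m <- measure_spine(mask, head_fraction = head_fraction)
    raw <- raw_metric(m$h, m$w_head, m$w_neck)
    rcw <- rcw_metric(m$h, m$w_head, m$w_neck)
    cls <- if (raw < raw_threshold) "thin"
           else if (rcw < rcw_threshold) "stubby"
           else "mushroom"
    out <- c(m, list(raw = raw, rcw = rcw, branched = FALSE,
                     shape_class = cls))
  }
  structure(out, class = "spine_metrics")
}

#' @export
print.spine_metrics <- function(x, ...) {
  if (x$branched) {
    cat("spine_metrics: branched-type (head width not meaningful)\n")
  } else {
    cat(sprintf(
      "spine_metrics: %s-type  h = %.2f  w_head = %.2f  w_neck = %.2f  RAW = %.3f  RCW = %.3f\n",
      x$shape_class, x$h, x$w_head, x$w_neck, x$raw, x$rcw))
  }
  invisible(x)
}

#' Extract and classify the newborn spine of a single-spine run
#'
#' Thresholds the final cytoskeleton field, keeps the connected component
#' containing the seed (detached blobs are ignored) and classifies the
#' newborn part above the seed's top row.
#'
#' @param traj an \code{rd_trajectory} from [simulate_spine()].
#' @param threshold silhouette threshold.
#' @return A \code{spine_metrics} object (see [classify_spine()]).
#' @export
measure_newborn_spine <- function(traj, threshold = 0.5) {
  stopifnot(inherits(traj, "rd_trajectory"))
  if (is.null(traj$seed_rows)) {
    stop("trajectory carries no seed annotation; use simulate_spine()")
  }
  st <- final_state(traj)
  m <- cell_mask(st$Y, threshold)
  nr <- nrow(m)
  seed_idx <- as.integer(outer(traj$seed_rows, (traj$seed_cols - 1L) * nr,
                               "+"))
  comp <- connected_component(m, seed_idx)
  classify_spine(spine_mask(comp, base_row = max(traj$seed_rows),
                            dx = traj$grid$dx))
}

#' Count spines and measure their density along a dendrite trunk
#'
#' Removes a vertical trunk band from the silhouette, labels the remaining
#' 4-connected components within a lateral root window, and counts
#' components of at least \code{min_area} pixels as spines.  The density
#' is the count divided by the trunk length.
#'
#' The band should cover the trunk and the thin parallel filaments that
#' hug it (see [trunk_band()], which measures the band from the stage-1
#' trunk with a default 5-px margin).  Counting is restricted to within
#' \code{reach} px of the band — spines are counted at their roots, so
#' distal canopies that merge or run along the domain walls do not corrupt
#' the count — and to rows up to \code{row_max} (the trunk extent;
#' arms formed by the growing trunk tip splitting are not spines).
#'
#' @param mask logical silhouette matrix.
#' @param band integer vector of trunk band column indices.
#' @param dx physical spacing.
#' @param min_area minimum component area in px (default 4).
#' @param reach lateral counting window beyond the band, in px
#'   (default 25).
#' @param row_max topmost row considered (default: all rows).
#' @return An object of class \code{"density_result"}: list with
#'   \code{spine_count}, \code{trunk_length} (physical units),
#'   \code{density} (count per unit length), and \code{labels} (the
#'   component label matrix of the counting window).
#' @export
spine_density <- function(mask, band, dx = 0.3, min_area = 4, reach = 25,
                          row_max = nrow(mask)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  band <- sort(unique(as.integer(band)))
  if (length(band) == 0 || !any(mask[, band])) {
    stop("trunk band is empty")
  }
  keep <- max(1, min(band) - reach):min(ncol(mask), max(band) + reach)
  m2 <- mask[seq_len(min(row_max, nrow(mask))), keep, drop = FALSE]
  m2[, keep %in% band] <- FALSE
  lab <- label_components(m2)
  sizes <- tabulate(lab[lab > 0])
  count <- sum(sizes >= min_area)
  trunk_rows <- which(rowSums(mask[, band, drop = FALSE]) > 0)
  trunk_length <- length(trunk_rows) * dx
  structure(list(spine_count = count, trunk_length = trunk_length,
                 density = count / trunk_length, labels = lab),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "density_result: %d spines along %.1f length units -> %.3f per unit\n",
    x$spine_count, x$trunk_length, x$density))
  invisible(x)
}

#' Trunk band of a dendrite simulation
#'
#' The column interval spanned by the stage-1 trunk silhouette, widened by
#' \code{margin} px on each side.  The margin (default 5) covers the thin
#' parallel filaments that develop alongside the trunk during stage 2, so
#' that [spine_density()] counts only true lateral protrusions.
#'
#' @param trunk_state the stage-1 final [rd_state()] (the \code{trunk}
#'   element of [run_dendrite_protocol()] output).
#' @param margin band margin in px.
#' @param threshold silhouette threshold.
#' @return Integer vector of column indices.
#' @export
trunk_band <- function(trunk_state, margin = 5, threshold = 0.5) {
  m <- cell_mask(trunk_state$Y, threshold)
  cols <- which(colSums(m) > 0)
  if (length(cols) == 0) stop("empty trunk")
  seq(min(cols) - margin, max(cols) + margin)
}

#' Spine count of a dendrite protocol run
#'
#' Convenience wrapper: thresholds the final state of a dendrite
#' trajectory, derives the trunk band and row cap from its stage-1 trunk,
#' and returns the [spine_density()] result.
#'
#' @param traj an \code{rd_trajectory} from [run_dendrite_protocol()].
#' @param ... passed to [spine_density()].
#' @return A \code{density_result}.
#' @export
dendrite_density <- function(traj, ...) {
  stopifnot(inherits(traj, "rd_trajectory"))
  if (is.null(traj$trunk)) stop("trajectory has no stage-1 trunk state")
  m <- cell_mask(final_state(traj)$Y)
  band <- trunk_band(traj$trunk)
  trunk_mask <- cell_mask(traj$trunk$Y)
  row_max <- max(which(rowSums(trunk_mask) > 0))
  spine_density(m, band, dx = traj$grid$dx, row_max = row_max, ...)
}
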