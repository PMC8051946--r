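#' Partition a recording into overall ROI, neurons, and background
#'
#' Given the inactivity-period mean intensity image and the hand-drawn
#' overall ROI (a mask around all labeled neurons), selects the brightest
#' 10% of pixels inside the overall ROI as the `neurons` region and the
#' dimmest 10% of pixels outside it as the `background` region. Decile
#' sizes are rounded up (`ceiling`), so tiny regions still yield at least
#' one pixel; intensity ties are broken deterministically by row-major
#' scan order (row, then column, origin top-left). An all-equal reference
#' image is flagged as degenerate.
#'
#' @param inactivity_mean Matrix of inactivity-period mean intensities.
#' @param overall_mask Logical matrix; must be non-empty and not
#'   full-frame (otherwise no background can be defined).
#' @param decile Fraction selected in each region (default 0.10).
#' @return An object of class `region_partition`: list of logical
#'   matrices `overall`, `neurons`, `background`, the `reference` image,
#'   and `degenerate` flag.
#' @export
region_partition <- function(inactivity_mean, overall_mask, decile = 0.10) {
  stopifnot(all(dim(inactivity_mean) == dim(overall_mask)))
  overall_mask <- overall_mask > 0
  n_in <- sum(overall_mask)
  n_out <- sum(!overall_mask)
  if (n_in == 0) stop("overall ROI is empty")
  if (n_out == 0) stop("overall ROI is full-frame: no background definable")
  ny <- nrow(inactivity_mean); nx <- ncol(inactivity_mean)
  ## rank within scan order: order(-intensity, scan_rank) etc.
  rows <- rep(seq_len(ny), times = nx)
  cols <- rep(seq_len(nx), each = ny)
  scan_rank <- (rows - 1) * nx + cols
  degenerate <- length(unique(inactivity_mean[overall_mask])) == 1 ||
    length(unique(inactivity_mean[!overall_mask])) == 1
  neurons <- matrix(FALSE, ny, nx)
  idx_in <- which(overall_mask)
  ord <- idx_in[order(-inactivity_mean[idx_in], scan_rank[idx_in])]
  neurons[ord[seq_len(ceiling(decile * n_in))]] <- TRUE
  background <- matrix(FALSE, ny, nx)
  idx_out <- which(!overall_mask)
  ord <- idx_out[order(inactivity_mean[idx_out], scan_rank[idx_out])]
  background[ord[seq_len(ceiling(decile * n_out))]] <- TRUE
  structure(list(overall = overall_mask, neurons = neurons,
                 background = background, reference = inactivity_mean,
                 degenerate = degenerate),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("Region partition: overall %d px, neurons %d px, background %d px%s\n",
              sum(x$overall), sum(x$neurons), sum(x$background),
              if (x$degenerate) " (degenerate: tie-broken by scan order)" else ""))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' 8-connectivity ("contiguous" includes diagonal neighbors), breadth-first
#' flood fill; labels are assigned in row-major scan order, so labeling is
#' deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels (0 = outside the mask).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  offs <- if (connectivity == 8) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))
  }
  current <- 0L
  stack <- integer(ny * nx)       # linear (column-major) pixel indices
  ## visit in row-major scan order for deterministic labels
  for (r in seq_len(ny)) for (cl in seq_len(nx)) {
    if (!mask[r, cl] || lab[r, cl] != 0L) next
    current <- current + 1L
    top <- 1L
    stack[1] <- (cl - 1L) * ny + r
    lab[r, cl] <- current
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      pr <- ((p - 1L) %% ny) + 1L
      pc <- ((p - 1L) %/% ny) + 1L
      for (o in seq_len(nrow(offs))) {
        rr <- pr + offs[o, 1]; cc <- pc + offs[o, 2]
        if (rr >= 1 && rr <= ny && cc >= 1 && cc <= nx &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- current
          top <- top + 1L
          stack[top] <- (cc - 1L) * ny + rr
        }
      }
    }
  }
  lab
}

#' Automatically generate tuning-based ROIs
#'
#' Discretizes a thresholded tuning map to the presented AoPs (each pixel
#' assigned to the band `[angle - step/2, angle + step/2)` in axial
#' distance; below-threshold pixels are null). For each presented angle,
#' finds the 8-connected components of its band, discards components
#' smaller than `min_px` pixels, and retains the largest surviving
#' component as that angle's ROI.
#'
#' @param map A [tuning_map()] (already thresholded), or a matrix of
#'   preferred angles with `NA` for excluded pixels.
#' @param presented_angles The AoPs presented in the tuning experiment
#'   (e.g. [aop_levels()] of the schedule).
#' @param min_px Minimum contiguous area in pixels (default 20).
#' @return An object of class `roi_set`: list with `rois` (a named list
#'   of logical masks, one per surviving angle, names the angle in
#'   degrees), and `summary` (tibble: `angle_deg`, `n_px`, `n_components`,
#'   `n_discarded`). An empty set is valid.
#' @export
auto_rois <- function(map, presented_angles, min_px = 20) {
  phi <- if (inherits(map, "tuning_map")) map$hue_deg else map
  half <- if (length(presented_angles) > 1) {
    min(diff(sort(presented_angles))) / 2
  } else {
    90
  }
  rois <- list()
  summ <- list()
  for (a in presented_angles) {
    d <- axial_diff(phi, a)
    band <- !is.na(phi) & d >= -half & d < half
    if (!any(band)) {
      summ[[length(summ) + 1]] <- tibble::tibble(
        angle_deg = a, n_px = 0L, n_components = 0L, n_discarded = 0L)
      next
    }
    lab <- label_components(band, connectivity = 8)
    sizes <- tabulate(lab[lab > 0])
    big <- which(sizes >= min_px)
    summ[[length(summ) + 1]] <- tibble::tibble(
      angle_deg = a,
      n_px = if (length(big)) max(sizes[big]) else 0L,
      n_components = length(sizes),
      n_discarded = length(sizes) - length(big))
    if (length(big) == 0) next
    winner <- big[which.max(sizes[big])]
    rois[[as.character(a)]] <- lab == winner
  }
  structure(list(rois = rois, summary = dplyr::bind_rows(summ),
                 min_px = min_px),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: %d ROI(s) (min %d px)\n", length(x$rois), x$min_px))
  if (length(x$rois)) print(x$summary[x$summary$n_px > 0, ])
  invisible(x)
}

#' Extract per-ROI raw time series
#'
#' Unweighted mean across member pixels per frame.
#'
#' @param frames An `ny x nx x nt` array (e.g. the `intensity` of an
#'   [inactivity_projection()]) or an `inactivity_projection`.
#' @param rois A `roi_set`, a single logical mask, or a (named) list of
#'   logical masks. Empty ROIs are rejected.
#' @return A tibble in long format: `roi`, `frame`, `f`.
#' @export
roi_timeseries <- function(frames, rois) {
  if (inherits(frames, "inactivity_projection")) frames <- frames$intensity
  stopifnot(length(dim(frames)) == 3)
  if (inherits(rois, "roi_set")) rois <- rois$rois
  if (is.matrix(rois) || is.logical(rois)) rois <- list(roi = rois)
  if (is.null(names(rois))) names(rois) <- seq_along(rois)
  d <- dim(frames)
  flat <- matrix(frames, d[1] * d[2], d[3])
  purrr::imap_dfr(rois, function(mask, nm) {
    stopifnot(all(dim(mask) == d[1:2]))
    idx <- which(mask)
    if (length(idx) == 0) stop("ROI '", nm, "' is empty")
    tibble::tibble(roi = nm, frame = seq_len(d[3]),
                   f = colMeans(flat[idx, , drop = FALSE]))
  })
}
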