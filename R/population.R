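#' Normalize unit positions along an image axis
#'
#' Projects pixel/ROI coordinates orthogonally onto the named image axis
#' (`"horizontal"` uses the x/column coordinate, `"vertical"` the y/row
#' coordinate) and min-max normalizes to `[0, 1]` within the recording.
#'
#' @param x,y Pixel coordinates.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return Normalized positions in `[0, 1]`.
#' @export
normalize_positions <- function(x, y, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  v <- if (axis == "horizontal") x else y
  as.vector(minmax_norm(v))
}

#' Invert a recording's positions for hemisphere pooling
#'
#' Left-hemisphere recordings are inverted along both image axes before
#' pooling with right-hemisphere recordings (so the expected
#' mirror-symmetric polarotopy lines up), i.e. a normalized position `p`
#' becomes `1 - p`. Applying the inversion twice restores the original
#' positions (involution).
#'
#' @param position Normalized positions in `[0, 1]`.
#' @param hemisphere `"left"` or `"right"` (vectorized); only left-side
#'   entries are inverted.
#' @return Positions after inversion.
#' @export
invert_hemisphere <- function(position, hemisphere) {
  stopifnot(all(hemisphere %in% c("left", "right")))
  ifelse(hemisphere == "left", 1 - position, position)
}

#' Pooled and per-recording polarotopy analysis
#'
#' Pools normalized positions and preferred AoPs across recordings (after
#' inverting left-hemisphere positions), fits the pooled circular-linear
#' regression with a permutation p-value, fits each recording
#' individually (with a smaller permutation test), combines per-recording
#' correlation coefficients into a Fisher-z mean across flies, and
#' attaches a hierarchical bootstrap BCa confidence interval when at
#' least two flies are present. A random subset of at most `subsample`
#' pooled points is retained for scatter plotting.
#'
#' @param data A data frame with columns `animal`, `recording`,
#'   `hemisphere` (`"left"`/`"right"`), `position` (normalized `[0, 1]`,
#'   pre-inversion), `aop_deg`, and optionally `psi`.
#' @param subsample Maximum scatter points kept (default 1000).
#' @param n_perm Permutations for the pooled test (default 10000).
#' @param n_perm_individual Permutations per recording (default 1000).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param min_points Minimum usable points for an individual fit
#'   (default 4); smaller recordings stay in the pool but are excluded
#'   from individual fits (logged in the output).
#' @param seed Seed for permutations, bootstrap and subsampling.
#' @return An object of class `polarotopy`: list with `pooled`
#'   (`circlin_fit` with `p_perm`), `per_recording` (tibble), `fisher_rho`
#'   (mean across flies), `ci` (`bootstrap_ci` or `NULL`), `scatter`
#'   (tibble), `n_excluded`, `seed`.
#' @export
polarotopy_analysis <- function(data, subsample = 1000, n_perm = 10000,
                                n_perm_individual = 1000, n_boot = 10000,
                                min_points = 4, seed = NULL) {
  req <- c("animal", "recording", "hemisphere", "position", "aop_deg")
  missing <- setdiff(req, names(data))
  if (length(missing)) stop("data is missing columns: ",
                            paste(missing, collapse = ", "))
  data <- tibble::as_tibble(data)
  data$position <- invert_hemisphere(data$position, data$hemisphere)
  if (!is.null(seed)) set.seed(seed)
  pooled <- circ_lin_fit(data$position, data$aop_deg)
  pooled$p_perm <- circ_lin_perm_test(data$position, data$aop_deg,
                                      n_perm = n_perm,
                                      seed = if (is.null(seed)) NULL else seed + 1L)$p_perm
  recs <- data |> dplyr::distinct(.data$animal, .data$recording)
  per_rec <- purrr::pmap_dfr(recs, function(animal, recording) {
    d <- data[data$animal == animal & data$recording == recording, ]
    if (nrow(d) < min_points || stats::sd(d$position) == 0) {
      return(tibble::tibble(animal = animal, recording = recording,
                            n = nrow(d), slope_cycles = NA_real_,
                            phase_deg = NA_real_, rho = NA_real_,
                            p_perm = NA_real_, excluded = TRUE))
    }
    fit <- circ_lin_fit(d$position, d$aop_deg)
    p <- circ_lin_perm_test(d$position, d$aop_deg,
                            n_perm = n_perm_individual,
                            seed = if (is.null(seed)) NULL else
                              seed + 100L + nrow(d))$p_perm
    tibble::tibble(animal = animal, recording = recording, n = nrow(d),
                   slope_cycles = fit$slope_cycles,
                   phase_deg = fit$phase_deg, rho = fit$rho,
                   p_perm = p, excluded = FALSE)
  })
  ok <- per_rec[!per_rec$excluded, ]
  fisher_rho <- if (nrow(ok)) fisher_mean(ok$rho) else NA_real_
  rho_by_fly <- split(ok$rho, ok$animal)
  ci <- if (length(rho_by_fly) >= 2) {
    hier_bootstrap_ci(rho_by_fly, n_boot = n_boot,
                      seed = if (is.null(seed)) NULL else seed + 2L)
  } else {
    NULL
  }
  n_keep <- min(subsample, nrow(data))
  if (!is.null(seed)) set.seed(seed + 3L)
  scatter <- data[sample.int(nrow(data), n_keep), ]
  structure(list(pooled = pooled, per_recording = per_rec,
                 fisher_rho = fisher_rho, ci = ci, scatter = scatter,
                 n_excluded = sum(per_rec$excluded), seed = seed),
            class = "polarotopy")
}

#' @export
print.polarotopy <- function(x, ...) {
  cat("Polarotopy analysis\n")
  cat(sprintf("  pooled: n = %d, rho = %.3f, p = %.3g\n",
              x$pooled$n, x$pooled$rho, x$pooled$p_perm))
  cat(sprintf("  per-recording: %d fits (%d excluded), Fisher-z mean rho = %.3f\n",
              sum(!x$per_recording$excluded), x$n_excluded, x$fisher_rho))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI: [%.3f, %.3f]\n", x$ci$lower, x$ci$upper))
  }
  invisible(x)
}

#' @export
tidy.polarotopy <- function(x, ...) {
  x$per_recording
}

#' @export
glance.polarotopy <- function(x, ...) {
  tibble::tibble(
    n_pooled = x$pooled$n,
    slope_cycles = x$pooled$slope_cycles,
    phase_deg = x$pooled$phase_deg,
    rho = x$pooled$rho,
    p_perm = x$pooled$p_perm,
    fisher_rho = x$fisher_rho,
    ci_lower = if (is.null(x$ci)) NA_real_ else x$ci$lower,
    ci_upper = if (is.null(x$ci)) NA_real_ else x$ci$upper,
    n_recordings = nrow(x$per_recording),
    n_excluded = x$n_excluded
  )
}

#' PSI-weighted population tuning vector
#'
#' The axial mean resultant vector of a recording's preferred angles. In
#' the pixel basis every pixel of the overall ROI contributes, weighted by
#' its PSI value rather than thresholded; in the ROI basis each ROI's
#' preferred angle is weighted by its mean PSI, and recordings with fewer
#' than `min_rois` ROIs are excluded. No grouping correction is applied
#' (preferred angles are continuous estimates, not grouped stimuli). A
#' length of 1 means an identical preferred AoP in every unit; 0 means a
#' uniform distribution.
#'
#' @param aop_deg Preferred angles (degrees).
#' @param weights PSI weights (same length); negative PSIs are clamped to
#'   zero weight.
#' @param basis `"pixel"` (default) or `"roi"`.
#' @param min_rois Minimum ROI count for the ROI basis (default 4).
#' @return A tibble with `angle_deg`, `length`, `basis`, `n`.
#' @export
population_vector <- function(aop_deg, weights = NULL,
                              basis = c("pixel", "roi"), min_rois = 4) {
  basis <- match.arg(basis)
  if (basis == "roi" && length(aop_deg) < min_rois) {
    stop("recording excluded: fewer than ", min_rois, " ROIs")
  }
  if (is.null(weights)) weights <- rep(1, length(aop_deg))
  weights <- pmax(weights, 0)
  am <- axial_mean(aop_deg, weights = weights)
  tibble::tibble(angle_deg = am$mean_deg, length = am$R, basis = basis,
                 n = length(aop_deg))
}

#' Area-true polar histogram of preferred angles
#'
#' Normalized probability per axial bin, with each bin drawn as a wedge
#' whose area (not radius) is proportional to its probability:
#' \eqn{r_k = \sqrt{p_k}}.
#'
#' @param aop_deg Preferred angles (degrees, axial).
#' @param bin_width Bin width in degrees; must divide 180 (default 15).
#' @return An object of class `polar_histogram`: tibble with `bin_lo`,
#'   `bin_hi`, `bin_mid`, `p` (probability) and `r` (wedge radius),
#'   carrying attribute `n`.
#' @export
polar_histogram <- function(aop_deg, bin_width = 15) {
  if (180 %% bin_width != 0) stop("bin_width must divide 180")
  aop <- wrap_axial(aop_deg)
  aop <- aop[!is.na(aop)]
  edges <- seq(-90, 90, by = bin_width)
  counts <- graphics::hist(aop, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  p <- counts / sum(counts)
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
    p = p,
    r = sqrt(p)
  )
  class(out) <- c("polar_histogram", class(out))
  attr(out, "n") <- length(aop)
  out
}

#' Fraction of above-threshold pixels in a region
#'
#' Recordings whose neurons region contains few polarization-selective
#' pixels (less than `min_frac` of the overall ROI above the PSI
#' threshold) are excluded from neurons-region polar histograms.
#'
#' @param psi_map Matrix of PSI values.
#' @param roi_mask Overall-ROI mask.
#' @param threshold PSI threshold.
#' @param min_frac Minimum above-threshold fraction (default 0.10).
#' @return Logical: does the recording qualify?
#' @export
has_enough_selective_pixels <- function(psi_map, roi_mask, threshold,
                                        min_frac = 0.10) {
  v <- psi_map[roi_mask]
  mean(!is.na(v) & v >= threshold) >= min_frac
}
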