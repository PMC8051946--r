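#' Polarization tuning curve of a single trace
#'
#' Averages raw fluorescence over the non-transition frames of each device
#' position (samples with time in `[t_on, t_off)`), then pools positions
#' presenting the same angle of polarization (diametrically opposite
#' device angles, across revolutions) into per-AoP means.
#'
#' @param f Raw fluorescence values of one pixel or ROI.
#' @param time_s Sample times.
#' @param schedule A polarizer-present `stim_schedule`.
#' @param min_samples Minimum usable samples required per position
#'   (default 1; the protocol guarantees >= 4 at >= 1 Hz volume rates, and
#'   fewer than `min_samples` in any position is an error).
#' @return An object of class `tuning_curve`: list with `angles_deg` (the
#'   K unique AoPs, sorted), `F_m` (per-AoP mean fluorescence),
#'   `per_presentation` (tibble in presentation order: `position`,
#'   `revolution`, `device_angle_deg`, `aop_deg`, `t_on`, `n_samples`,
#'   `f_mean`), and `step_angle_deg`.
#' @export
tuning_curve <- function(f, time_s, schedule, min_samples = 1) {
  stopifnot(inherits(schedule, "stim_schedule"))
  if (!schedule$polarizer_present) {
    stop("tuning_curve requires a polarizer-present schedule")
  }
  stopifnot(length(f) == length(time_s))
  p <- schedule$positions
  pres <- p |>
    dplyr::mutate(
      f_mean = vapply(seq_len(nrow(p)), function(i) {
        sel <- time_s >= p$t_on[i] & time_s < p$t_off[i]
        if (sum(sel) == 0) return(NA_real_)
        mean(f[sel])
      }, numeric(1)),
      n_samples = vapply(seq_len(nrow(p)), function(i) {
        sum(time_s >= p$t_on[i] & time_s < p$t_off[i])
      }, integer(1))
    )
  if (any(pres$n_samples < min_samples)) {
    stop("position(s) ", paste(pres$position[pres$n_samples < min_samples],
                               collapse = ", "),
         " have fewer than ", min_samples, " usable (non-transition) samples")
  }
  by_aop <- pres |>
    dplyr::group_by(.data$aop_deg) |>
    dplyr::summarise(F_m = mean(.data$f_mean), .groups = "drop") |>
    dplyr::arrange(.data$aop_deg)
  structure(list(angles_deg = by_aop$aop_deg, F_m = by_aop$F_m,
                 per_presentation = pres[, c("position", "revolution",
                                             "device_angle_deg", "aop_deg",
                                             "t_on", "n_samples", "f_mean")],
                 step_angle_deg = schedule$step_angle_deg),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("Polarization tuning curve:\n")
  print(tibble::tibble(aop_deg = x$angles_deg, F_m = x$F_m))
  invisible(x)
}

#' Preferred angle of polarization of a tuning curve
#'
#' The angle of the weighted axial mean resultant vector of the presented
#' AoPs, weighted by the per-AoP mean fluorescence, with the grouped-data
#' correction for the stimulus step spacing.
#'
#' @param curve A [tuning_curve()].
#' @return A list with `phi_deg` (in `[-90, 90)`, `NA` when undefined),
#'   `R` (grouping-corrected resultant length) and `defined`.
#' @export
preferred_aop <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  if (any(curve$F_m < 0)) stop("tuning-curve weights must be non-negative")
  if (!any(curve$F_m > 0)) stop("all-zero tuning curve: preferred angle undefined")
  am <- axial_mean(curve$angles_deg, weights = curve$F_m,
                   grouping_deg = curve$step_angle_deg)
  list(phi_deg = am$mean_deg, R = am$R, defined = am$defined)
}

## index of the presented AoP axially nearest phi; ties broken toward the
## AoP whose first presentation occurred earlier
nearest_aop_index <- function(angles_deg, phi_deg, first_pres_time) {
  d <- axial_dist(angles_deg, phi_deg)
  cand <- which(abs(d - min(d)) < 1e-9)
  if (length(cand) > 1) cand <- cand[which.min(first_pres_time[cand])]
  cand
}

#' Polarization-selectivity index of a tuning curve
#'
#' Selects the presented AoP axially closest to the preferred angle
#' (`phi_deg`), averages the raw fluorescence over the first two
#' presentations in time of that AoP (its device position and the
#' diametrically opposite one, 180 degrees apart, both within the first
#' revolution by construction) to obtain `F_pref`, does the same at the
#' orthogonal AoP for `F_ortho`, and returns
#' \deqn{PSI = (F_{pref} - F_{ortho}) / (F_{pref} + F_{ortho}).}
#' Equal responses at all angles give 0; zero orthogonal response gives 1.
#' Values below 0 can occur when the resultant-vector angle does not
#' maximize the first-two-presentation mean (e.g. under drift) and are
#' reported as computed.
#'
#' @param curve A [tuning_curve()].
#' @param phi_deg Preferred AoP in degrees (e.g. from [preferred_aop()]).
#' @return A tibble with `aop_pref_deg`, `aop_ortho_deg`, `f_pref`,
#'   `f_ortho` and `psi`.
#' @export
psi <- function(curve, phi_deg) {
  stopifnot(inherits(curve, "tuning_curve"))
  pres <- curve$per_presentation
  first_time <- vapply(curve$angles_deg, function(a) {
    min(pres$t_on[axial_dist(pres$aop_deg, a) < 1e-9])
  }, numeric(1))
  i_pref <- nearest_aop_index(curve$angles_deg, phi_deg, first_time)
  i_orth <- nearest_aop_index(curve$angles_deg,
                              curve$angles_deg[i_pref] + 90, first_time)
  mean_first_two <- function(aop) {
    rows <- pres[axial_dist(pres$aop_deg, aop) < 1e-9, ]
    rows <- rows[order(rows$t_on), ]
    mean(rows$f_mean[seq_len(min(2, nrow(rows)))])
  }
  f_pref <- mean_first_two(curve$angles_deg[i_pref])
  f_orth <- mean_first_two(curve$angles_deg[i_orth])
  if (f_pref + f_orth == 0) {
    stop("F_pref + F_ortho = 0: PSI undefined")
  }
  tibble::tibble(
    aop_pref_deg = curve$angles_deg[i_pref],
    aop_ortho_deg = curve$angles_deg[i_orth],
    f_pref = f_pref, f_ortho = f_orth,
    psi = (f_pref - f_orth) / (f_pref + f_orth)
  )
}

#' Change in PSI relative to polarizer-removed controls
#'
#' Subtracts the mean control PSI (same region, polarizer removed) from
#' each test PSI value.
#'
#' @param psi_values Test PSI values.
#' @param control_psi_values PSI values from polarizer-removed control
#'   experiments in the matching region; must be non-empty.
#' @return `psi_values - mean(control_psi_values)`.
#' @seealso [delta_psi_summary()] for the per-animal reporting convention.
#' @export
delta_psi <- function(psi_values, control_psi_values) {
  if (length(control_psi_values) == 0) stop("empty control set")
  psi_values - mean(control_psi_values)
}

#' Summarize ΔPSI the way population values are reported
#'
#' PSI distributions within a recording tend to be non-normal, so the
#' median is reported per animal and the mean of the per-animal medians
#' across animals.
#'
#' @param data A data frame with columns `animal` and `psi`.
#' @param control_psi_values Control PSI values (polarizer removed).
#' @return A tibble with one row per animal (`animal`, `median_psi`,
#'   `median_delta_psi`) plus attribute `mean_of_medians`.
#' @export
delta_psi_summary <- function(data, control_psi_values) {
  if (length(control_psi_values) == 0) stop("empty control set")
  ctrl <- mean(control_psi_values)
  out <- data |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(median_psi = stats::median(.data$psi), .groups = "drop") |>
    dplyr::mutate(median_delta_psi = .data$median_psi - ctrl)
  structure2(out, mean_of_medians = mean(out$median_delta_psi),
             control_mean = ctrl)
}

#' PSI threshold from a reference distribution
#'
#' Mean + 1 SD (sample SD, n-1 denominator) of the reference PSI values.
#' The default reference is the background region of the recording; for
#' bridge (E-PG) recordings — where neuron PSIs averaged over many
#' presentations tend to be lower than background — use the PSI values
#' within neurons across all polarizer-removed tuning experiments instead.
#'
#' @param reference_psi PSI values of the reference set (non-empty).
#' @return The threshold (scalar).
#' @export
psi_threshold <- function(reference_psi) {
  if (length(reference_psi) == 0) stop("reference set is empty")
  s <- if (length(reference_psi) > 1) stats::sd(reference_psi) else 0
  mean(reference_psi) + s
}

#' Per-pixel tuning of an inactivity projection
#'
#' Vectorized tuning analysis of every pixel in an
#' [inactivity_projection()]: per-position means (using each pixel's own
#' source-plane acquisition times), per-AoP pooling, preferred angle via
#' the grouping-corrected axial mean, and PSI from the first two
#' presentations at the preferred and orthogonal angles.
#'
#' @param projection An `inactivity_projection`.
#' @param schedule A polarizer-present `stim_schedule` (defaults to the
#'   projection's).
#' @return A tibble with one row per pixel: `row`, `col`, `phi_deg`, `R`,
#'   `f_pref`, `f_ortho`, `psi`, `f0_inactivity`. Carries the matrices as
#'   attributes `phi_map`, `psi_map`, `r_map` and a list attribute
#'   `aop_curves` (`n_pixel x K` matrix of per-AoP means, plus
#'   `angles_deg`).
#' @export
pixel_tuning <- function(projection, schedule = NULL) {
  stopifnot(inherits(projection, "inactivity_projection"))
  schedule <- schedule %||% projection$schedule
  if (!schedule$polarizer_present) {
    stop("pixel_tuning requires a polarizer-present schedule")
  }
  d <- dim(projection$intensity)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  Fmat <- matrix(projection$intensity, ny * nx, nt)
  p <- schedule$positions
  npos <- nrow(p)
  angles <- sort(unique(p$aop_deg))
  K <- length(angles)
  ## per-plane position-assignment matrices (plane times differ slightly)
  P <- matrix(NA_real_, ny * nx, npos)
  for (z in sort(unique(as.vector(projection$plane_index)))) {
    tz <- projection$frame_times[z, seq_len(nt)]
    M <- matrix(0, nt, npos)
    for (i in seq_len(npos)) {
      sel <- tz >= p$t_on[i] & tz < p$t_off[i]
      if (!any(sel)) stop("position ", i, " has no usable frames in plane ", z)
      M[sel, i] <- 1 / sum(sel)
    }
    rows <- which(projection$plane_index == z)
    P[rows, ] <- Fmat[rows, , drop = FALSE] %*% M
  }
  ## per-AoP means over all presentations
  Aind <- vapply(angles, function(a) {
    as.numeric(axial_dist(p$aop_deg, a) < 1e-9)
  }, numeric(npos))
  Aind <- sweep(Aind, 2, colSums(Aind), "/")
  FM <- P %*% Aind                                     # n_pixel x K
  ## axial mean with grouping correction, vectorized
  cc <- cos(2 * deg2rad(angles)); ss <- sin(2 * deg2rad(angles))
  Csum <- FM %*% cc; Ssum <- FM %*% ss
  wsum <- rowSums(FM)
  R <- sqrt(Csum^2 + Ssum^2) / wsum
  R <- pmin(1, R * grouping_correction(schedule$step_angle_deg))
  phi <- wrap_axial(rad2deg(atan2(Ssum, Csum) / 2))
  phi[R <= sqrt(.Machine$double.eps)] <- NA_real_
  ## first-two-presentation means per AoP (columns ordered like `angles`)
  FP <- matrix(0, ny * nx, K)
  first_time <- numeric(K)
  for (j in seq_len(K)) {
    rows <- which(axial_dist(p$aop_deg, angles[j]) < 1e-9)
    rows <- rows[order(p$t_on[rows])][seq_len(min(2, length(rows)))]
    FP[, j] <- rowMeans(P[, rows, drop = FALSE])
    first_time[j] <- min(p$t_on[rows])
  }
  sel_pref <- integer(ny * nx); sel_orth <- integer(ny * nx)
  for (i in seq_len(ny * nx)) {
    if (is.na(phi[i])) {
      sel_pref[i] <- NA_integer_; sel_orth[i] <- NA_integer_
    } else {
      sel_pref[i] <- nearest_aop_index(angles, phi[i], first_time)
      sel_orth[i] <- nearest_aop_index(angles, angles[sel_pref[i]] + 90,
                                       first_time)
    }
  }
  f_pref <- FP[cbind(seq_len(ny * nx), sel_pref)]
  f_orth <- FP[cbind(seq_len(ny * nx), sel_orth)]
  psi_v <- (f_pref - f_orth) / (f_pref + f_orth)
  psi_v[!is.finite(psi_v)] <- NA_real_
  out <- tibble::tibble(
    row = rep(seq_len(ny), times = nx),
    col = rep(seq_len(nx), each = ny),
    phi_deg = as.vector(phi), R = as.vector(R),
    f_pref = f_pref, f_ortho = f_orth, psi = psi_v,
    f0_inactivity = as.vector(projection$inactivity_mean)
  )
  structure2(out,
             phi_map = matrix(phi, ny, nx),
             psi_map = matrix(psi_v, ny, nx),
             r_map = matrix(R, ny, nx),
             aop_curves = list(F_m = FM, angles_deg = angles),
             step_angle_deg = schedule$step_angle_deg)
}

#' Compose a polarization tuning map
#'
#' Combines a hue layer (preferred AoP, 180-degree periodic color wheel)
#' for pixels inside the overall ROI whose PSI passes the threshold, with
#' a normalized grayscale layer (inactivity-mean intensity, scaled between
#' its 1st and 99th percentiles to resist hot pixels) for every other
#' pixel. Every pixel belongs to exactly one layer.
#'
#' @param phi_map Matrix of preferred AoPs (degrees).
#' @param psi_map Matrix of PSI values.
#' @param threshold PSI threshold (see [psi_threshold()]).
#' @param roi_mask Logical matrix: the overall ROI.
#' @param inactivity_mean Matrix of inactivity-period mean intensities.
#' @return An object of class `tuning_map`: list with `hue_deg` (AoP, `NA`
#'   outside the hue layer), `gray` (normalized intensity, `NA` inside the
#'   hue layer), and `threshold`.
#' @export
tuning_map <- function(phi_map, psi_map, threshold, roi_mask,
                       inactivity_mean) {
  stopifnot(all(dim(phi_map) == dim(psi_map)),
            all(dim(phi_map) == dim(roi_mask)),
            all(dim(phi_map) == dim(inactivity_mean)))
  in_hue <- roi_mask & !is.na(psi_map) & psi_map >= threshold &
    !is.na(phi_map)
  q <- stats::quantile(inactivity_mean, c(0.01, 0.99), names = FALSE)
  gray <- if (q[2] > q[1]) {
    pmin(pmax((inactivity_mean - q[1]) / (q[2] - q[1]), 0), 1)
  } else {
    matrix(0, nrow(inactivity_mean), ncol(inactivity_mean))
  }
  hue <- phi_map; hue[!in_hue] <- NA_real_
  gray[in_hue] <- NA_real_
  structure(list(hue_deg = hue, gray = gray, threshold = threshold),
            class = "tuning_map")
}

#' @export
print.tuning_map <- function(x, ...) {
  cat(sprintf("Tuning map: %d x %d px, %d hue (above-threshold) pixels, threshold %.3f\n",
              nrow(x$hue_deg), ncol(x$hue_deg), sum(!is.na(x$hue_deg)),
              x$threshold))
  invisible(x)
}

#' Trigonometric (Fourier-domain) interpolation of a periodic curve
#'
#' Resamples a uniformly sampled periodic curve to `n_out` points by
#' zero-padding its DFT; evaluated at the original sample points the
#' interpolant reproduces the input exactly.
#'
#' @param y Samples over one period (uniform spacing).
#' @param n_out Output length (`>= length(y)`).
#' @return Interpolated values (length `n_out`).
#' @export
fourier_interp <- function(y, n_out) {
  m <- length(y)
  stopifnot(n_out >= m)
  if (n_out == m) return(y)
  Y <- stats::fft(y)
  out <- complex(n_out)
  half <- floor(m / 2)
  out[1:(half + 1)] <- Y[1:(half + 1)]
  if (half >= 1) {
    neg <- (m - ceiling(m / 2) + 2):m          # negative-frequency block
    if (m %% 2 == 0) {
      ## even length: split the Nyquist bin between +/- frequencies
      out[half + 1] <- Y[half + 1] / 2
      out[n_out - half + 1] <- Y[half + 1] / 2
      if (half >= 2) out[(n_out - half + 2):n_out] <- Y[(half + 2):m]
    } else {
      out[(n_out - half + 1):n_out] <- Y[(half + 2):m]
    }
  }
  Re(stats::fft(out, inverse = TRUE)) / m
}

#' Aligned average normalized tuning curve
#'
#' For each pixel, the per-AoP tuning curve is normalized
#' (\eqn{\Delta F/F = F_m/F_0 - 1} with the inactivity-period mean as
#' `F_0`), interpolated in the Fourier domain to 360 samples over the
#' 180-degree axial period (0.5-degree resolution), circularly shifted so
#' the pixel's preferred angle (rounded to the nearest degree) sits at the
#' first sample, and averaged across pixels.
#'
#' @param F_m Matrix `n_pixel x K` of per-AoP mean fluorescence.
#' @param angles_deg The K presented AoPs (sorted ascending).
#' @param phi_deg Per-pixel preferred angles.
#' @param F0 Per-pixel inactivity baselines; pixels with `F0 <= 0` are
#'   excluded (count reported in attribute `n_excluded`).
#' @param n_out Number of resampled points (default 360).
#' @return A tibble with `offset_deg` (angle relative to preferred, in
#'   `[-90, 90)`) and `dff` (average normalized response), attribute
#'   `n_pixels` and `n_excluded`.
#' @export
aligned_average_curve <- function(F_m, angles_deg, phi_deg, F0,
                                  n_out = 360) {
  F_m <- rbind(F_m)
  n_px <- nrow(F_m); K <- ncol(F_m)
  stopifnot(length(angles_deg) == K, length(phi_deg) == n_px,
            length(F0) == n_px)
  keep <- which(F0 > 0 & !is.na(phi_deg))
  n_excluded <- n_px - length(keep)
  if (length(keep) == 0) stop("no pixels with positive baseline")
  deg_per_sample <- 180 / n_out
  acc <- numeric(n_out)
  for (i in keep) {
    dff <- F_m[i, ] / F0[i] - 1
    ## reorder so the curve starts at the first presented angle
    up <- fourier_interp(dff, n_out)
    ## sample j (1-based) corresponds to AoP angles_deg[1] + (j-1)*0.5 deg
    phi_r <- round(phi_deg[i])
    shift <- round((phi_r - angles_deg[1]) / deg_per_sample) %% n_out
    ## rotate so the preferred angle lands at sample 1
    aligned <- up[((seq_len(n_out) - 1 + shift) %% n_out) + 1]
    acc <- acc + aligned
  }
  avg <- acc / length(keep)
  offset <- wrap_axial((seq_len(n_out) - 1) * deg_per_sample)
  ord <- order(offset)
  structure2(tibble::tibble(offset_deg = offset[ord], dff = avg[ord]),
             n_pixels = length(keep), n_excluded = n_excluded)
}

#' Polarization-versus-bar activity difference map
#'
#' Per-pixel SD of fluorescence across the polarization-experiment frames
#' and across the bar-experiment frames; each activity map is min-max
#' normalized, then the bar map is subtracted from the polarization map.
#' Positive values mark polarization-dominated pixels, negative values
#' bar-dominated ones.
#'
#' @param frames_pol,frames_bar `ny x nx x nt` arrays of co-registered
#'   frames from the two experiments.
#' @return A matrix (the difference map) with attribute `flat` flagging a
#'   zero-variance (degenerate) input map.
#' @export
activity_difference_map <- function(frames_pol, frames_bar) {
  stopifnot(all(dim(frames_pol)[1:2] == dim(frames_bar)[1:2]))
  px_sd <- function(a) apply(a, c(1, 2), stats::sd)
  m_pol <- minmax_norm(px_sd(frames_pol))
  m_bar <- minmax_norm(px_sd(frames_bar))
  out <- m_pol - m_bar
  attr(out, "flat") <- isTRUE(attr(m_pol, "flat")) ||
    isTRUE(attr(m_bar, "flat"))
  out
}
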