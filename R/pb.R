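#' Circular distance between positions on the 8-glomerulus ring
#'
#' Glomerulus pairs occupy an 8-position ring; the distance between two
#' positions is the shorter way around, in `{0, 1, 2, 3, 4}`.
#'
#' @param i,j Positions (1-8, vectorized).
#' @return Integer distances.
#' @export
ring_distance <- function(i, j) {
  d <- abs(i - j) %% 8
  pmin(d, 8 - d)
}

#' Zero-lag cross-correlation of left/right glomerulus pairs
#'
#' Under the wrapped pairing scheme selected by `shift`, computes the
#' mean-subtracted normalized cross-correlation coefficient at zero lag
#' (the Pearson correlation) for each of the 8 left/right pairs over the
#' full recording, and their mean after the Fisher z-transformation.
#' Pairs with a zero-variance member are excluded (counted in the
#' output).
#'
#' @param recording A `pb_recording` (see [make_pb_dataset()]) or a
#'   matrix of 16 columns named `1L..8L, 1R..8R`.
#' @param shift Pairing-scheme shift, 0-7.
#' @return A list with `pairs` (tibble: `pair`, `left`, `right`, `rho`)
#'   and `mean_rho` (Fisher-z mean over defined pairs), `n_excluded`.
#' @export
pairing_correlation <- function(recording, shift) {
  traces <- if (inherits(recording, "pb_recording")) recording$traces else recording
  stopifnot(ncol(traces) == 16)
  scheme <- pb_pair_scheme(shift)
  rho <- vapply(seq_len(8), function(j) {
    a <- traces[, scheme$left[j]]
    b <- traces[, 8 + scheme$right[j]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  pairs <- dplyr::mutate(scheme, rho = rho)
  n_excluded <- sum(is.na(rho))
  mean_rho <- if (all(is.na(rho))) NA_real_ else
    suppressWarnings(fisher_mean(rho))
  list(pairs = pairs, mean_rho = mean_rho, n_excluded = n_excluded)
}

#' Find the best left/right pairing scheme
#'
#' Evaluates all 8 wrapped pairing schemes with [pairing_correlation()]
#' and returns the shift maximizing the Fisher-z mean coefficient, with
#' the full profile. For phase-staggered tuned glomeruli the profile
#' falls off sinusoidally as the pairing distance from the true scheme
#' grows. Ties are reported at the smallest shift and flagged.
#'
#' @inheritParams pairing_correlation
#' @return A list with `shift` (the argmax), `profile` (tibble: `shift`,
#'   `mean_rho`), `tie` flag.
#' @export
best_pairing <- function(recording) {
  profile <- purrr::map_dfr(0:7, function(s) {
    tibble::tibble(shift = s,
                   mean_rho = pairing_correlation(recording, s)$mean_rho)
  })
  best <- max(profile$mean_rho, na.rm = TRUE)
  hits <- profile$shift[!is.na(profile$mean_rho) &
                          abs(profile$mean_rho - best) < 1e-12]
  list(shift = min(hits), profile = profile, tie = length(hits) > 1)
}

#' Pool the paired left/right glomerulus series
#'
#' Arithmetic mean of each pair's raw left and right series under the
#' given pairing scheme, before any tuning analysis.
#'
#' @inheritParams pairing_correlation
#' @return A matrix `nt x 8` of pooled pair series (columns = pairs).
#' @export
pb_pool_pairs <- function(recording, shift) {
  traces <- if (inherits(recording, "pb_recording")) recording$traces else recording
  scheme <- pb_pair_scheme(shift)
  out <- vapply(seq_len(8), function(j) {
    (traces[, scheme$left[j]] + traces[, 8 + scheme$right[j]]) / 2
  }, numeric(nrow(traces)))
  colnames(out) <- paste0("pair", 1:8)
  out
}

#' Auto-correlation peak shift and phase locking
#'
#' Restricts the series to the first two tuning cycles (two 180-degree
#' sweeps), removes a linear trend, computes the normalized
#' auto-correlation, locates the first strict local maximum at lags
#' beyond `min_lag_frac` of the stimulus period (skipping the shoulder of
#' slow-indicator smoothing), and reports the absolute difference between
#' that lag and the stimulus period (the AoP period: one 180-degree
#' sweep). The response is phase-locked when the peak shift is at most
#' `window_s` (default half the angle-presentation duration, 2 s for 4 s
#' holds).
#'
#' @param f Fluorescence series of one ROI.
#' @param time_s Sample times.
#' @param schedule The tuning `stim_schedule`.
#' @param window_s Phase-lock window half-width; defaults to
#'   [phase_lock_window_s()] of the schedule.
#' @param min_lag_frac First-peak search starts at this fraction of the
#'   period (default 0.25).
#' @return A tibble with `peak_lag_s` (`NA` when no local maximum is
#'   found), `peak_shift_s`, `phase_locked`, `period_s`.
#' @export
autocorr_peak_shift <- function(f, time_s, schedule, window_s = NULL,
                                min_lag_frac = 0.25) {
  stopifnot(inherits(schedule, "stim_schedule"), length(f) == length(time_s))
  period <- aop_period_s(schedule)
  window_s <- window_s %||% phase_lock_window_s(schedule)
  t0 <- schedule$positions$t_on[1]
  sel <- time_s >= t0 & time_s < t0 + 2 * period
  if (sum(sel) < 8) stop("series does not span the first two tuning cycles")
  y <- f[sel]; tt <- time_s[sel]
  ## linear detrend
  y <- stats::resid(stats::lm(y ~ tt))
  dt <- stats::median(diff(tt))
  ## per-lag Pearson autocorrelation: demeaning and normalizing each
  ## lagged segment separately avoids both the triangular taper of the
  ## biased estimator and the partial-period bias of a global demeaning,
  ## either of which drags the first peak off the true period
  n <- length(y)
  max_lag <- floor(0.75 * n)
  ac <- vapply(0:max_lag, function(k) {
    stats::cor(y[seq_len(n - k)], y[(k + 1):n])
  }, numeric(1))
  lags <- (seq_along(ac) - 1) * dt
  start <- which(lags >= min_lag_frac * period)[1]
  peak_lag <- NA_real_
  if (!is.na(start)) {
    for (i in seq(max(start, 2), length(ac) - 1)) {
      if (!anyNA(ac[(i - 1):(i + 1)]) &&
          ac[i] > ac[i - 1] && ac[i] > ac[i + 1]) {
        peak_lag <- lags[i]
        break
      }
    }
  }
  if (is.na(peak_lag)) {
    return(tibble::tibble(peak_lag_s = NA_real_, peak_shift_s = NA_real_,
                          phase_locked = FALSE, period_s = period))
  }
  shift <- abs(peak_lag - period)
  tibble::tibble(peak_lag_s = peak_lag, peak_shift_s = shift,
                 phase_locked = shift <= window_s, period_s = period)
}

#' Cycle-by-cycle tuning of pooled glomerulus pairs
#'
#' Splits the tuning experiment into individual cycles (one 180-degree
#' sweep each: `180 / step_angle_deg` consecutive positions, roughly 30 s
#' for the default protocol) and, per cycle and per pooled pair, computes
#' the tuning curve over that cycle's angles, the preferred AoP via the
#' grouping-corrected axial mean, and a within-cycle PSI (preferred vs
#' orthogonal presentations of that cycle). Incomplete trailing cycles
#' are dropped.
#'
#' @param paired Matrix `nt x n_pair` of pooled pair series (see
#'   [pb_pool_pairs()]).
#' @param time_s Sample times.
#' @param schedule The tuning `stim_schedule`.
#' @param cycle `"half_rev"` (default: one 180-degree sweep) or
#'   `"full_rev"` (a full device revolution).
#' @return An object of class `cycle_tuning`: tibble with `cycle`,
#'   `pair`, `aop_deg`, `R`, `psi`, plus attribute `cycle_mean_psi`
#'   (tibble: `cycle`, `mean_psi`) and `n_dropped` (incomplete cycles).
#' @export
cycle_tuning <- function(paired, time_s, schedule,
                         cycle = c("half_rev", "full_rev")) {
  cycle <- match.arg(cycle)
  stopifnot(inherits(schedule, "stim_schedule"))
  paired <- cbind(paired)
  p <- schedule$positions
  per_cycle <- if (cycle == "half_rev") 180 / schedule$step_angle_deg else
    360 / schedule$step_angle_deg
  n_cycles <- floor(nrow(p) / per_cycle)
  n_dropped <- (nrow(p) %% per_cycle > 0)
  if (n_cycles < 1) stop("schedule contains no complete cycle")
  res <- list()
  for (cy in seq_len(n_cycles)) {
    rows <- ((cy - 1) * per_cycle + 1):(cy * per_cycle)
    pc <- p[rows, ]
    for (j in seq_len(ncol(paired))) {
      fm <- vapply(seq_len(nrow(pc)), function(i) {
        sel <- time_s >= pc$t_on[i] & time_s < pc$t_off[i]
        mean(paired[sel, j])
      }, numeric(1))
      am <- axial_mean(pc$aop_deg, weights = pmax(fm, 0),
                       grouping_deg = schedule$step_angle_deg)
      ## within-cycle PSI: preferred vs orthogonal presentations of this
      ## cycle only
      phi <- if (am$defined) am$mean_deg else NA_real_
      psi_v <- NA_real_
      if (!is.na(phi)) {
        i_pref <- nearest_aop_index(pc$aop_deg, phi, pc$t_on)
        i_orth <- nearest_aop_index(pc$aop_deg, pc$aop_deg[i_pref] + 90,
                                    pc$t_on)
        fp <- fm[i_pref]; fo <- fm[i_orth]
        if (fp + fo != 0) psi_v <- (fp - fo) / (fp + fo)
      }
      res[[length(res) + 1]] <- tibble::tibble(
        cycle = cy, pair = j, aop_deg = phi, R = am$R, psi = psi_v)
    }
  }
  out <- dplyr::bind_rows(res)
  cm <- out |>
    dplyr::group_by(.data$cycle) |>
    dplyr::summarise(mean_psi = mean(.data$psi, na.rm = TRUE),
                     .groups = "drop")
  out <- structure2(out, cycle_mean_psi = cm, n_dropped = n_dropped)
  class(out) <- c("cycle_tuning", class(out))
  out
}

#' G0-referenced tuning-shift distribution
#'
#' Draws (with the given seed) one stimulus cycle in which the mean PSI
#' across glomerulus pairs exceeds `threshold`, takes the pair with the
#' maximum PSI in that cycle as the reference G0, and tabulates each
#' pair's circular ring distance from G0 (0-4) against the axial
#' difference of its preferred AoP from G0's (0-90 degrees).
#'
#' @param ct A [cycle_tuning()] result.
#' @param threshold Qualifying mean-PSI threshold (E-PG mode
#'   [psi_threshold()], i.e. from polarizer-removed neuron PSIs).
#' @param seed Seed for the random cycle draw.
#' @return A tibble with `pair`, `rel_pos` (ring distance from G0),
#'   `rel_aop_deg` (axial shift, `[0, 90]`), `cycle` (the drawn cycle)
#'   and `g0` (the reference pair), or an error if no cycle qualifies.
#' @export
g0_shift_analysis <- function(ct, threshold, seed = NULL) {
  stopifnot(inherits(ct, "cycle_tuning"))
  cm <- attr(ct, "cycle_mean_psi")
  qual <- cm$cycle[!is.na(cm$mean_psi) & cm$mean_psi > threshold]
  if (length(qual) == 0) {
    stop("no cycle exceeds the mean-PSI threshold; recording excluded")
  }
  if (!is.null(seed)) set.seed(seed)
  cy <- if (length(qual) == 1) qual else sample(qual, 1)
  d <- ct[ct$cycle == cy, ]
  g0 <- d$pair[which.max(d$psi)]
  aop0 <- d$aop_deg[d$pair == g0]
  tibble::tibble(
    pair = d$pair,
    rel_pos = ring_distance(d$pair, g0),
    rel_aop_deg = axial_dist(d$aop_deg, aop0),
    cycle = cy,
    g0 = g0
  )
}
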