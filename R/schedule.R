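#' Build a stepped-polarizer stimulus schedule
#'
#' Constructs the timed sequence of polarizer positions for a tuning
#' experiment: the polarizer is rotated discontinuously in `step_angle_deg`
#' increments, each position held for `hold_s` seconds (optionally jittered
#' uniformly on `[hold_s, hold_s + 0.5]`), with `transition_s` seconds of
#' rotation between positions, over `n_revolutions` full 360-degree device
#' revolutions. A 10 s inactivity window (darkness, no stimulation) is
#' prepended and appended, matching the spontaneous-activity periods
#' recorded between stimulus sets.
#'
#' With the polarizer present, position `k` (0-based) presents the angle of
#' polarization `(k * step_angle_deg) mod 180`, so each revolution contains
#' `360 / step_angle_deg` device positions and `180 / step_angle_deg`
#' unique AoPs, each presented twice (at diametrically opposite device
#' angles). With the polarizer removed the light is unpolarized and
#' `aop_deg` is `NA`.
#'
#' @param step_angle_deg Angular increment per position, in degrees; must
#'   divide 180 (default 30).
#' @param hold_s Hold duration per position in seconds (default 4).
#' @param transition_s Rotation duration between positions (default 0.5).
#' @param n_revolutions Number of full device revolutions (default 2).
#' @param polarizer_present Logical; `FALSE` models the polarizer-removed
#'   control (default `TRUE`).
#' @param inactivity_s Duration of the pre/post inactivity windows
#'   (default 10).
#' @param hold_jitter Draw each hold duration uniformly from
#'   `[hold_s, hold_s + 0.5]` (default `FALSE`, fixed holds).
#' @param seed Seed for the jitter draws (only used when `hold_jitter`).
#' @return An object of class `stim_schedule`: a list with the call
#'   parameters plus `positions` (tibble: `position`, `revolution`,
#'   `device_angle_deg`, `aop_deg`, `t_on`, `t_off`), `inactivity_windows`
#'   (tibble: `t_start`, `t_end`), `light_events` (tibble: `event`,
#'   `time_s`) and `duration_s`.
#' @export
#' @examples
#' sched <- make_schedule(30, 4, 0.5, 2)
#' nrow(sched$positions)                      # 24 positions
#' length(unique(sched$positions$aop_deg))    # 6 unique AoPs
make_schedule <- function(step_angle_deg = 30, hold_s = 4, transition_s = 0.5,
                          n_revolutions = 2, polarizer_present = TRUE,
                          inactivity_s = 10, hold_jitter = FALSE,
                          seed = NULL) {
  if (step_angle_deg <= 0 || 180 %% step_angle_deg != 0) {
    stop("step_angle_deg must be a positive divisor of 180 (and hence of 360); got ",
         step_angle_deg)
  }
  stopifnot(hold_s > 0, transition_s >= 0, n_revolutions >= 1,
            inactivity_s >= 0)
  n_per_rev <- 360 / step_angle_deg
  n_pos <- as.integer(n_revolutions * n_per_rev)
  holds <- if (hold_jitter) {
    if (!is.null(seed)) set.seed(seed)
    stats::runif(n_pos, hold_s, hold_s + 0.5)
  } else {
    rep(hold_s, n_pos)
  }
  k <- seq_len(n_pos) - 1L
  t_on <- inactivity_s + cumsum(c(0, holds[-n_pos] + transition_s))
  t_off <- t_on + holds
  stim_end <- t_off[n_pos] + transition_s
  positions <- tibble::tibble(
    position = k + 1L,
    revolution = k %/% as.integer(n_per_rev) + 1L,
    device_angle_deg = (k * step_angle_deg) %% 360,
    aop_deg = if (polarizer_present) wrap_axial(k * step_angle_deg) else NA_real_,
    t_on = t_on,
    t_off = t_off
  )
  structure(list(
    step_angle_deg = step_angle_deg,
    hold_s = hold_s,
    transition_s = transition_s,
    n_revolutions = n_revolutions,
    polarizer_present = polarizer_present,
    inactivity_s = inactivity_s,
    positions = positions,
    inactivity_windows = tibble::tibble(
      t_start = c(0, stim_end),
      t_end = c(inactivity_s, stim_end + inactivity_s)
    ),
    light_events = tibble::tibble(
      event = c("on", "off"),
      time_s = c(inactivity_s, stim_end)
    ),
    duration_s = stim_end + inactivity_s
  ), class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "Stimulus schedule: %g deg steps, %d revolution(s), polarizer %s\n",
    x$step_angle_deg, x$n_revolutions,
    if (x$polarizer_present) "present" else "removed"))
  cat(sprintf("  %d positions (%g per revolution, %g unique AoPs), hold %g s, transition %g s\n",
              nrow(x$positions), 360 / x$step_angle_deg,
              180 / x$step_angle_deg, x$hold_s, x$transition_s))
  cat(sprintf("  total duration %.1f s (incl. 2 x %g s inactivity)\n",
              x$duration_s, x$inactivity_s))
  invisible(x)
}

#' Unique angles of polarization presented by a schedule
#'
#' @param schedule A [make_schedule()] object.
#' @return Sorted unique AoPs in degrees (`[-90, 90)`), or `numeric(0)` for
#'   a polarizer-removed schedule.
#' @export
aop_levels <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  if (!schedule$polarizer_present) return(numeric(0))
  sort(unique(schedule$positions$aop_deg))
}

#' Duration of one 180-degree AoP sweep
#'
#' One tuning cycle covers `180 / step_angle_deg` consecutive positions;
#' its nominal duration is that count times `hold_s + transition_s`
#' (27 s for the default 30-degree, 4 s + 0.5 s protocol).
#'
#' @inheritParams aop_levels
#' @return Cycle period in seconds.
#' @export
aop_period_s <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  (180 / schedule$step_angle_deg) * (schedule$hold_s + schedule$transition_s)
}

#' Phase-locking window half-width for a schedule
#'
#' Half the duration of each angle presentation: the maximum expected
#' auto-correlation peak shift for a response phase-locked to the stimulus
#' (2 s for the default 4 s holds).
#'
#' @inheritParams aop_levels
#' @return Half-width in seconds.
#' @export
phase_lock_window_s <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  schedule$hold_s / 2
}

## is each time inside some inactivity window (inclusive start, exclusive end)
in_inactivity <- function(schedule, time_s) {
  w <- schedule$inactivity_windows
  out <- rep(FALSE, length(time_s))
  for (i in seq_len(nrow(w))) {
    out <- out | (time_s >= w$t_start[i] & time_s < w$t_end[i])
  }
  out
}

## position index (or NA) of each time; holds only, transitions excluded
position_at <- function(schedule, time_s) {
  p <- schedule$positions
  idx <- rep(NA_integer_, length(time_s))
  for (i in seq_len(nrow(p))) {
    sel <- time_s >= p$t_on[i] & time_s < p$t_off[i]
    idx[sel] <- p$position[i]
  }
  idx
}
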