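#' Simulate a polarization-tuned fluorescence response
#'
#' Generates a noiseless-or-noisy fluorescence trace for a neuron with a
#' sinusoidal axial tuning. During a hold at angle of polarization
#' \eqn{\theta} (polarizer present) the mean level is
#' \deqn{B (1 + A \cos 2(\theta - \varphi))}
#' with preferred angle \eqn{\varphi}, modulation depth `A` and baseline
#' `B`. With the polarizer removed the level is
#' \eqn{B (1 + s A)} throughout the light-on period, with
#' `unpolarized_sign` `s = -1` modeling suppression by unpolarized light
#' (the default) and `s = +1` excitation. During inactivity windows the
#' level is `B`. Transition periods ramp linearly between the neighboring
#' hold levels. The level trace is convolved with a causal
#' single-exponential indicator kernel (time constant `tau_s`; `0`
#' disables it), then Gaussian noise is added and the result clipped at 0
#' (intensities are non-negative).
#'
#' @param schedule A [make_schedule()] object.
#' @param phi_deg Preferred AoP in degrees (axial; any representative of
#'   the mod-180 class).
#' @param A Modulation depth in `[0, 1]`.
#' @param B Baseline fluorescence, `> 0`.
#' @param unpolarized_sign `-1` (suppression, default) or `+1`
#'   (excitation) under unpolarized light.
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed Seed for the noise draws.
#' @param rate_hz Sampling rate of the trace (default 10).
#' @param tau_s Indicator decay time constant in seconds (default 1; `0`
#'   for no kernel).
#' @param times Optional explicit sample times (overrides `rate_hz`); must
#'   be increasing and evenly spaced when `tau_s > 0`.
#' @return A tibble with `time_s`, `mu` (noiseless post-kernel level) and
#'   `f` (observed fluorescence).
#' @export
#' @examples
#' sched <- make_schedule()
#' tr <- simulate_response(sched, phi_deg = 30, A = 0.8, B = 100)
simulate_response <- function(schedule, phi_deg, A, B, unpolarized_sign = -1,
                              noise_sd = 0, seed = NULL, rate_hz = 10,
                              tau_s = 1, times = NULL) {
  stopifnot(inherits(schedule, "stim_schedule"))
  if (!(B > 0)) stop("baseline B must be positive")
  if (A < 0 || A > 1) stop("modulation depth A must lie in [0, 1]")
  stopifnot(unpolarized_sign %in% c(-1, 1))
  if (is.null(times)) {
    times <- seq(0, schedule$duration_s, by = 1 / rate_hz)
  }
  mu <- response_level(schedule, times, phi_deg, A, B, unpolarized_sign)
  if (tau_s > 0) {
    dt <- if (length(times) > 1) stats::median(diff(times)) else 1 / rate_hz
    mu <- exp_kernel_filter(mu, dt, tau_s)
  }
  f <- mu
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd))
  }
  tibble::tibble(time_s = times, mu = mu, f = f)
}

## instantaneous (pre-kernel) level at arbitrary times, with linear ramps
## across transitions
response_level <- function(schedule, times, phi_deg, A, B, unpolarized_sign) {
  p <- schedule$positions
  hold_level <- if (schedule$polarizer_present) {
    B * (1 + A * cos(2 * deg2rad(p$aop_deg - phi_deg)))
  } else {
    rep(B * (1 + unpolarized_sign * A), nrow(p))
  }
  lev <- rep(B, length(times))
  for (i in seq_len(nrow(p))) {
    sel <- times >= p$t_on[i] & times < p$t_off[i]
    lev[sel] <- hold_level[i]
    ## transition after position i: ramp to the next hold level (or to
    ## baseline after the last position, when the light goes off)
    if (schedule$transition_s > 0) {
      t0 <- p$t_off[i]; t1 <- t0 + schedule$transition_s
      nxt <- if (i < nrow(p)) hold_level[i + 1] else B
      selt <- times >= t0 & times < t1
      frac <- (times[selt] - t0) / (t1 - t0)
      lev[selt] <- hold_level[i] + frac * (nxt - hold_level[i])
    }
  }
  lev
}

## causal single-exponential filter, unit-sum kernel, initialized at the
## first sample so a constant input stays constant
exp_kernel_filter <- function(x, dt, tau_s) {
  alpha <- 1 - exp(-dt / tau_s)
  out <- numeric(length(x))
  state <- x[1]
  for (i in seq_along(x)) {
    state <- state + alpha * (x[i] - state)
    out[i] <- state
  }
  out
}

#' Describe a synthetic imaging scene
#'
#' A scene holds the ground truth that [render_volume()] turns into a
#' two-channel imaging volume: the neurons (position, footprint, tuning),
#' background level, rigid per-frame motion, and noise.
#'
#' @param neurons A data frame with one row per neuron and columns `x`,
#'   `y` (centroid, pixels, may be fractional), `z` (plane, integer),
#'   `radius_px` (footprint radius), `phi_deg` (preferred AoP),
#'   `A` (modulation depth), `baseline` (B), and optionally
#'   `unpolarized_sign` (default -1).
#' @param background Constant background intensity added to both channels
#'   (default 10).
#' @param noise_sd Per-voxel Gaussian noise SD (default 0).
#' @param motion Either `NULL` (no motion) or a two-column matrix/data
#'   frame of per-frame `(dx, dy)` shifts in pixels (recycled or truncated
#'   to the number of frames).
#' @param tau_s Indicator kernel time constant passed to
#'   [simulate_response()] (default 1).
#' @return An object of class `synth_scene`.
#' @export
make_scene <- function(neurons, background = 10, noise_sd = 0, motion = NULL,
                       tau_s = 1) {
  neurons <- tibble::as_tibble(neurons)
  req <- c("x", "y", "z", "radius_px", "phi_deg", "A", "baseline")
  missing <- setdiff(req, names(neurons))
  if (length(missing)) stop("neurons is missing columns: ",
                            paste(missing, collapse = ", "))
  if (!"unpolarized_sign" %in% names(neurons)) neurons$unpolarized_sign <- -1
  structure(list(neurons = neurons, background = background,
                 noise_sd = noise_sd, motion = motion, tau_s = tau_s),
            class = "synth_scene")
}

#' Arrange neurons on a linear polarotopy gradient
#'
#' Convenience constructor: `n` neurons evenly spaced along the x axis
#' whose preferred AoP varies linearly with position (one axial sweep from
#' `aop_start` over `aop_span` degrees), emulating a polarotopic map.
#'
#' @param n Number of neurons.
#' @param shape Volume shape `c(ny, nx, nz)` the neurons must fit.
#' @param aop_start,aop_span Gradient intercept and span in degrees
#'   (default -90 and 180: one full axial cycle).
#' @param A,baseline,radius_px Tuning parameters shared by all neurons.
#' @param jitter_px Vertical jitter of centroids (default 0).
#' @param seed Seed for the jitter.
#' @return A `neurons` tibble for [make_scene()], with the extra column
#'   `position_norm` (normalized 0-1 gradient position) and `neuron` id.
#' @export
gradient_neurons <- function(n, shape, aop_start = -90, aop_span = 180,
                             A = 0.8, baseline = 100, radius_px = 2,
                             jitter_px = 0, seed = NULL) {
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  margin <- ceiling(2.5 * radius_px) + 1
  xs <- seq(margin, nx - margin, length.out = n)
  pos <- (xs - min(xs)) / (max(xs) - min(xs))
  ys <- rep(ny / 2, n)
  if (jitter_px > 0) {
    if (!is.null(seed)) set.seed(seed)
    ys <- ys + stats::runif(n, -jitter_px, jitter_px)
  }
  tibble::tibble(
    neuron = seq_len(n),
    x = xs, y = ys, z = rep_len(seq_len(nz), n),
    radius_px = radius_px,
    phi_deg = wrap_axial(aop_start + aop_span * pos),
    A = A, baseline = baseline,
    position_norm = pos
  )
}

## truncated gaussian footprint of one neuron on an (ny, nx) grid
neuron_footprint <- function(x, y, radius_px, ny, nx) {
  sigma <- radius_px / 2
  r <- ceiling(2.5 * sigma)
  rows <- max(1, floor(y - r)):min(ny, ceiling(y + r))
  cols <- max(1, floor(x - r)):min(nx, ceiling(x + r))
  if (length(rows) == 0 || length(cols) == 0) {
    stop("neuron footprint falls outside the volume bounds")
  }
  d2 <- outer((rows - y)^2, (cols - x)^2, "+")
  w <- exp(-d2 / (2 * sigma^2))
  w[sqrt(d2) > 2.5 * sigma] <- 0
  list(rows = rows, cols = cols, w = w)
}

#' Render a synthetic two-channel imaging volume
#'
#' Turns a [make_scene()] description into an `imaging_volume`: the
#' activity channel is the background plus each neuron's spatial footprint
#' scaled by its [simulate_response()] trace (sampled at that neuron's
#' plane acquisition times); the structural channel is the static
#' footprints (scaled by baseline) plus background. Per-frame rigid motion
#' is applied identically to both channels, then noise.
#'
#' @param scene A `synth_scene`.
#' @param schedule A [make_schedule()] object.
#' @param shape Volume shape `c(ny, nx, nz)`.
#' @param rate_hz Volume rate in Hz (default 2; must give at least 1
#'   volume per second of schedule time).
#' @param seed Seed for all noise draws.
#' @return A list with `volume` (class `imaging_volume`: channels
#'   `activity` and `structure` as `(ny, nx, nz, nt)` arrays, `frame_times`
#'   an `nz x nt` matrix, `rate_hz`, `schedule`) and `scene` (the ground
#'   truth, with per-neuron traces attached as a list-column `trace`).
#' @export
render_volume <- function(scene, schedule, shape, rate_hz = 2, seed = NULL) {
  stopifnot(inherits(scene, "synth_scene"), inherits(schedule, "stim_schedule"))
  if (rate_hz < 1) stop("volume rate must be at least 1 Hz")
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  nt <- floor(schedule$duration_s * rate_hz) + 1L
  plane_dt <- (1 / rate_hz) / nz
  frame_times <- outer(seq_len(nz) - 1, seq_len(nt) - 1,
                       function(z, k) k / rate_hz + z * plane_dt)
  if (!is.null(seed)) set.seed(seed)
  neurons <- scene$neurons
  fps <- vector("list", nrow(neurons))
  traces <- vector("list", nrow(neurons))
  for (i in seq_len(nrow(neurons))) {
    nr <- neurons[i, ]
    if (nr$x < 1 || nr$x > nx || nr$y < 1 || nr$y > ny || nr$z < 1 ||
        nr$z > nz) {
      stop("neuron ", i, " centroid outside the volume bounds")
    }
    fps[[i]] <- neuron_footprint(nr$x, nr$y, nr$radius_px, ny, nx)
    traces[[i]] <- simulate_response(
      schedule, phi_deg = nr$phi_deg, A = nr$A, B = nr$baseline,
      unpolarized_sign = nr$unpolarized_sign, noise_sd = 0,
      tau_s = scene$tau_s, times = frame_times[nr$z, ])$mu
  }
  act <- array(scene$background, dim = c(ny, nx, nz, nt))
  str <- array(scene$background, dim = c(ny, nx, nz, nt))
  for (i in seq_len(nrow(neurons))) {
    fp <- fps[[i]]; z <- neurons$z[i]
    for (k in seq_len(nt)) {
      act[fp$rows, fp$cols, z, k] <- act[fp$rows, fp$cols, z, k] +
        fp$w * traces[[i]][k]
    }
    str_add <- fp$w * neurons$baseline[i]
    for (k in seq_len(nt)) {
      str[fp$rows, fp$cols, z, k] <- str[fp$rows, fp$cols, z, k] + str_add
    }
  }
  if (!is.null(scene$motion)) {
    mo <- as.matrix(scene$motion)
    if (ncol(mo) != 2) stop("motion must have two columns (dx, dy)")
    mo <- mo[rep_len(seq_len(nrow(mo)), nt), , drop = FALSE]
    for (k in seq_len(nt)) {
      if (mo[k, 1] != 0 || mo[k, 2] != 0) {
        for (z in seq_len(nz)) {
          act[, , z, k] <- shift_image(act[, , z, k], mo[k, 1], mo[k, 2])
          str[, , z, k] <- shift_image(str[, , z, k], mo[k, 1], mo[k, 2])
        }
      }
    }
  }
  if (scene$noise_sd > 0) {
    act <- pmax(0, act + stats::rnorm(length(act), 0, scene$noise_sd))
    str <- pmax(0, str + stats::rnorm(length(str), 0, scene$noise_sd))
    dim(act) <- c(ny, nx, nz, nt); dim(str) <- c(ny, nx, nz, nt)
  }
  scene$neurons$trace <- traces
  scene$neurons$footprint_sum <- vapply(fps, function(f) sum(f$w), numeric(1))
  volume <- structure(list(
    channels = list(activity = act, structure = str),
    frame_times = frame_times, rate_hz = rate_hz, schedule = schedule
  ), class = "imaging_volume")
  list(volume = volume, scene = scene)
}

#' @export
print.imaging_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Imaging volume: %d x %d px, %d plane(s), %d frames at %g Hz; channels: %s\n",
              d[1], d[2], d[3], d[4], x$rate_hz,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

## wrapped left/right pairing scheme on the 16-glomerulus bridge:
## shift 0 pairs 1L/1R, 8L/2R, 7L/3R, ... (each side wraps independently)
pb_pair_scheme <- function(shift) {
  stopifnot(shift %in% 0:7)
  tibble::tibble(
    pair = 1:8,
    left = c(1L, 8L, 7L, 6L, 5L, 4L, 3L, 2L),
    right = ((0:7 + shift) %% 8L) + 1L
  )
}

#' Generate a synthetic protocerebral-bridge dataset
#'
#' Produces 16 glomerulus traces (8 left, 1L-8L; 8 right, 1R-8R) under a
#' tuning schedule. Each of the 8 ground-truth pairs responds with a
#' sinusoidal axial tuning at its own preferred AoP (`phases`); under the
#' wrapped pairing scheme selected by `pairing_shift`, each right-side
#' trace duplicates its ground-truth partner's left-side trace plus
#' independent noise.
#'
#' @param schedule A [make_schedule()] object.
#' @param pairing_shift Integer 0-7 selecting the true wrapped pairing
#'   scheme (0 pairs 1L/1R, 8L/2R, 7L/3R, ...).
#' @param phases Length-8 vector of per-pair preferred AoPs (degrees).
#'   Default staggers them evenly over the axial range.
#' @param A,B,tau_s Response-model parameters shared by all pairs.
#' @param noise_sd Independent Gaussian noise SD added to every trace.
#' @param rate_hz Sampling rate (default 10).
#' @param seed Seed for the noise.
#' @return An object of class `pb_recording`: list with `traces` (matrix
#'   `nt x 16`, columns `1L..8L, 1R..8R`), `time_s`, `schedule`, and
#'   `truth` (`pairing_shift`, `phases` per pair).
#' @export
make_pb_dataset <- function(schedule, pairing_shift = 0,
                            phases = wrap_axial(seq(0, by = 22.5, length.out = 8)),
                            A = 1, B = 100, noise_sd = 0, rate_hz = 10,
                            tau_s = 1, seed = NULL) {
  stopifnot(inherits(schedule, "stim_schedule"))
  if (length(phases) != 8) stop("phases must have 8 entries (one per pair)")
  if (!pairing_shift %in% 0:7) stop("pairing_shift must be in 0..7")
  if (!is.null(seed)) set.seed(seed)
  scheme <- pb_pair_scheme(pairing_shift)
  times <- seq(0, schedule$duration_s, by = 1 / rate_hz)
  nt <- length(times)
  traces <- matrix(0, nt, 16)
  colnames(traces) <- c(paste0(1:8, "L"), paste0(1:8, "R"))
  for (j in 1:8) {
    mu <- simulate_response(schedule, phi_deg = phases[j], A = A, B = B,
                            noise_sd = 0, tau_s = tau_s, times = times)$mu
    left_col <- scheme$left[j]
    right_col <- 8 + scheme$right[j]
    traces[, left_col] <- mu
    traces[, right_col] <- mu
  }
  if (noise_sd > 0) {
    noisy <- pmax(0, traces + stats::rnorm(length(traces), 0, noise_sd))
    traces[] <- noisy
  }
  structure(list(traces = traces, time_s = times, schedule = schedule,
                 truth = list(pairing_shift = pairing_shift, phases = phases)),
            class = "pb_recording")
}

#' @export
print.pb_recording <- function(x, ...) {
  cat(sprintf("PB recording: 16 glomerulus traces, %d samples, true pairing shift %d\n",
              nrow(x$traces), x$truth$pairing_shift))
  invisible(x)
}
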