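#' Shift an image by a (possibly subpixel) rigid translation
#'
#' Bilinear interpolation with edge replication. A positive `dx` moves
#' content toward larger column indices, positive `dy` toward larger row
#' indices.
#'
#' @param img Numeric matrix.
#' @param dx,dy Shift in pixels (columns, rows).
#' @return The shifted matrix.
#' @export
shift_image <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- seq_len(ny) - dy
  xs <- seq_len(nx) - dx
  y0 <- pmin(pmax(floor(ys), 1), ny); y1 <- pmin(y0 + 1, ny)
  x0 <- pmin(pmax(floor(xs), 1), nx); x1 <- pmin(x0 + 1, nx)
  fy <- pmin(pmax(ys - floor(ys), 0), 1); fy[ys < 1] <- 0; fy[ys > ny] <- 0
  fx <- pmin(pmax(xs - floor(xs), 0), 1); fx[xs < 1] <- 0; fx[xs > nx] <- 0
  A <- img[y0, x0, drop = FALSE]; B <- img[y1, x0, drop = FALSE]
  C <- img[y0, x1, drop = FALSE]; D <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, ny, nx); wx <- matrix(fx, ny, nx, byrow = TRUE)
  (1 - wy) * (1 - wx) * A + wy * (1 - wx) * B +
    (1 - wy) * wx * C + wy * wx * D
}

## upsampled cross-correlation in a small neighborhood via matrix-multiply
## DFT (the standard efficient subpixel registration refinement)
dft_upsample_cc <- function(X, row_center, col_center, upsample, half_width) {
  ny <- nrow(X); nx <- ncol(X)
  n_pts <- ceiling(2 * half_width * upsample) + 1
  rows <- row_center + (seq_len(n_pts) - 1 - (n_pts - 1) / 2) / upsample
  cols <- col_center + (seq_len(n_pts) - 1 - (n_pts - 1) / 2) / upsample
  fy <- c(0:floor((ny - 1) / 2), -(ceiling((ny - 1) / 2):1)) / ny
  fx <- c(0:floor((nx - 1) / 2), -(ceiling((nx - 1) / 2):1)) / nx
  Er <- exp(2i * pi * outer(rows, fy))        # n_pts x ny
  Ec <- exp(2i * pi * outer(fx, cols))        # nx x n_pts
  CCu <- Er %*% X %*% Ec
  peak <- which(Mod(CCu) == max(Mod(CCu)), arr.ind = TRUE)[1, ]
  c(dy = rows[peak[1]], dx = cols[peak[2]])
}

#' Estimate the rigid shift between two images
#'
#' Fourier cross-correlation with subpixel refinement by local DFT
#' upsampling. Returns the shift `(dx, dy)` that, applied to `img` with
#' [shift_image()], best aligns it to `ref` — i.e. the correction, the
#' negative of the motion that displaced `img` relative to `ref`.
#'
#' @param ref,img Numeric matrices of equal size.
#' @param upsample Subpixel upsampling factor (default 20, i.e. 1/20 px).
#' @return Named numeric vector `c(dx, dy)`.
#' @export
estimate_shift <- function(ref, img, upsample = 20) {
  stopifnot(all(dim(ref) == dim(img)))
  ny <- nrow(ref); nx <- ncol(ref)
  F1 <- stats::fft(ref - mean(ref))
  F2 <- stats::fft(img - mean(img))
  X <- F1 * Conj(F2)
  cc <- stats::fft(X, inverse = TRUE)
  peak <- which(Mod(cc) == max(Mod(cc)), arr.ind = TRUE)[1, ]
  dy <- peak[1] - 1; dx <- peak[2] - 1
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  if (upsample > 1) {
    sub <- dft_upsample_cc(X, dy, dx, upsample, half_width = 1.5)
    dy <- sub["dy"]; dx <- sub["dx"]
  }
  c(dx = unname(dx), dy = unname(dy))
}

#' Register an imaging volume on its structural channel
#'
#' Estimates per-frame rigid in-plane shifts on the maximum-intensity
#' projection of the activity-independent structural channel, against the
#' time-average of that projection as reference, then applies the same
#' shifts to every plane of every channel (including the activity
#' channel). Shifts are subpixel (DFT upsampling, default 1/20 px);
#' interpolation is bilinear with edge replication.
#'
#' @param volume An `imaging_volume` (see [render_volume()]).
#' @param channel Channel used for estimation (default `"structure"`).
#' @param upsample Subpixel upsampling factor (default 20).
#' @return A list with `volume` (corrected) and `shifts`, a tibble with
#'   one row per frame: `frame`, `dx`, `dy`, `flagged` (`TRUE` for
#'   all-zero frames, which get a zero shift).
#' @export
register_volume <- function(volume, channel = "structure", upsample = 20) {
  stopifnot(inherits(volume, "imaging_volume"))
  if (!channel %in% names(volume$channels)) {
    stop("structural channel '", channel, "' not present")
  }
  arr <- volume$channels[[channel]]
  d <- dim(arr)
  if (d[4] < 2) stop("registration requires at least 2 frames")
  ## per-frame MIP across planes
  mip <- array(0, dim = c(d[1], d[2], d[4]))
  for (k in seq_len(d[4])) {
    mip[, , k] <- apply(arr[, , , k, drop = FALSE], c(1, 2), max)
  }
  ref <- apply(mip, c(1, 2), mean)
  shifts <- tibble::tibble(frame = seq_len(d[4]), dx = 0, dy = 0,
                           flagged = FALSE)
  for (k in seq_len(d[4])) {
    frame <- mip[, , k]
    if (all(frame == 0)) {
      shifts$flagged[k] <- TRUE
      next
    }
    s <- estimate_shift(ref, frame, upsample = upsample)
    shifts$dx[k] <- s["dx"]; shifts$dy[k] <- s["dy"]
  }
  corrected <- volume
  for (ch in names(volume$channels)) {
    a <- volume$channels[[ch]]
    for (k in seq_len(d[4])) {
      if (shifts$dx[k] != 0 || shifts$dy[k] != 0) {
        for (z in seq_len(d[3])) {
          a[, , z, k] <- shift_image(a[, , z, k], shifts$dx[k], shifts$dy[k])
        }
      }
    }
    corrected$channels[[ch]] <- a
  }
  list(volume = corrected, shifts = shifts)
}

#' Inactivity-based maximum-intensity projection
#'
#' For each imaging plane, averages the frames whose full acquisition
#' interval lies inside an inactivity window; the plane with the highest
#' inactivity-period average at each `(x, y)` is selected, and that
#' pixel's entire time series is taken from that single fixed plane.
#' Neighboring pixels may therefore come from different planes, but each
#' pixel's series originates from exactly one plane — avoiding the bias of
#' a plain maximum projection toward neurons bright throughout the
#' recording.
#'
#' @param volume An `imaging_volume`.
#' @param schedule A `stim_schedule`; defaults to the one stored in the
#'   volume.
#' @param channel Channel to project (default `"activity"`).
#' @return An object of class `inactivity_projection`: list with
#'   `intensity` (`ny x nx x nt`), `plane_index` (`ny x nx`),
#'   `inactivity_mean` (`ny x nx`, from the selected plane), `frame_times`
#'   (`nz x nt`), `rate_hz`, `schedule`.
#' @export
inactivity_projection <- function(volume, schedule = NULL,
                                  channel = "activity") {
  stopifnot(inherits(volume, "imaging_volume"))
  schedule <- schedule %||% volume$schedule
  stopifnot(inherits(schedule, "stim_schedule"))
  arr <- volume$channels[[channel]]
  d <- dim(arr)
  nz <- d[3]; nt <- d[4]
  plane_len <- (1 / volume$rate_hz) / nz
  means <- array(NA_real_, dim = c(d[1], d[2], nz))
  any_frames <- FALSE
  for (z in seq_len(nz)) {
    t0 <- volume$frame_times[z, ]
    ok <- in_inactivity(schedule, t0) & in_inactivity(schedule, t0 + plane_len)
    if (!any(ok)) next
    any_frames <- TRUE
    means[, , z] <- apply(arr[, , z, ok, drop = FALSE], c(1, 2), mean)
  }
  if (!any_frames) {
    stop("no frames fall entirely within an inactivity window; ",
         "cannot build the inactivity projection")
  }
  plane_index <- apply(means, c(1, 2), function(v) {
    if (all(is.na(v))) NA_integer_ else which.max(v)
  })
  if (anyNA(plane_index)) stop("some planes have no inactivity frames")
  intensity <- array(0, dim = c(d[1], d[2], nt))
  inactivity_mean <- matrix(0, d[1], d[2])
  for (z in seq_len(nz)) {
    sel <- plane_index == z
    if (!any(sel)) next
    plane <- arr[, , z, ]
    dim(plane) <- c(d[1] * d[2], nt)
    flat_sel <- which(sel)
    intensity_flat <- matrix(intensity, d[1] * d[2], nt)
    intensity_flat[flat_sel, ] <- plane[flat_sel, ]
    intensity <- array(intensity_flat, dim = c(d[1], d[2], nt))
    m <- means[, , z]
    inactivity_mean[sel] <- m[sel]
  }
  structure(list(intensity = intensity, plane_index = plane_index,
                 inactivity_mean = inactivity_mean,
                 frame_times = volume$frame_times,
                 rate_hz = volume$rate_hz, schedule = schedule),
            class = "inactivity_projection")
}

#' @export
print.inactivity_projection <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("Inactivity projection: %d x %d px, %d frames, %d source plane(s)\n",
              d[1], d[2], d[3], length(unique(as.vector(x$plane_index)))))
  invisible(x)
}

#' Normalize a fluorescence trace to \eqn{\Delta F/F}
#'
#' Computes `dff = f / F0 - 1`. For polarization-tuning experiments the
#' baseline `F0` is the root mean square of the whole-experiment trace
#' (`"rms_whole"`); for all other experiments it is the mean of the 0.5 s
#' preceding stimulus onset (`"prestim_500ms"`, onset taken from the
#' schedule's first light-on event).
#'
#' @param f Raw fluorescence values.
#' @param time_s Sample times (required for `"prestim_500ms"`).
#' @param schedule A `stim_schedule` (required for `"prestim_500ms"`).
#' @param baseline_mode `"rms_whole"` (default) or `"prestim_500ms"`.
#' @return A tibble with `time_s`, `f` and `dff`, carrying attributes
#'   `F0` and `baseline_mode`.
#' @export
#' @examples
#' normalize_trace(c(3, 4))           # F0 = sqrt((9 + 16)/2)
normalize_trace <- function(f, time_s = NULL, schedule = NULL,
                            baseline_mode = c("rms_whole", "prestim_500ms")) {
  baseline_mode <- match.arg(baseline_mode)
  if (!any(f > 0)) stop("trace must be positive somewhere")
  if (baseline_mode == "rms_whole") {
    F0 <- sqrt(mean(f^2))
  } else {
    if (is.null(time_s) || is.null(schedule)) {
      stop("prestim_500ms mode needs sample times and a schedule")
    }
    onset <- schedule$light_events$time_s[schedule$light_events$event == "on"][1]
    sel <- time_s >= onset - 0.5 & time_s < onset
    if (!any(sel)) stop("no samples in the 0.5 s pre-stimulus window")
    F0 <- mean(f[sel])
  }
  if (!(F0 > 0)) stop("baseline F0 is not positive; cannot normalize")
  tibble::tibble(
    time_s = if (is.null(time_s)) seq_along(f) else time_s,
    f = f, dff = f / F0 - 1
  ) |>
    structure2(F0 = F0, baseline_mode = baseline_mode)
}

## attach attributes without disturbing tibble class
structure2 <- function(x, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  x
}

#' Resample a trace onto a common time base
#'
#' Linear interpolation, used when averaging across recordings with
#' mismatched sampling rates.
#'
#' @param f Values; `time_s` their times; `new_time_s` the target times.
#' @return Interpolated values at `new_time_s` (rule-2 edge handling).
#' @export
resample_trace <- function(f, time_s, new_time_s) {
  stats::approx(time_s, f, xout = new_time_s, rule = 2)$y
}
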