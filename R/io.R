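#' Write an imaging volume to TIFF files with a JSON sidecar
#'
#' One multi-page 16-bit TIFF per channel (pages ordered plane-fastest:
#' page = (frame - 1) * nz + plane), plus a JSON sidecar holding the
#' dimensions, frame times, intensity scale, schedule parameters, and
#' optional ground truth. Intensities are stored as
#' `round(value / scale * 65535)` with `scale = max(value)`.
#'
#' @param volume An `imaging_volume`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files.
#' @param truth Optional list of ground-truth metadata for the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_imaging_volume <- function(volume, dir, name = "volume",
                                 truth = NULL) {
  stopifnot(inherits(volume, "imaging_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$channels[[1]])
  scales <- list()
  for (ch in names(volume$channels)) {
    arr <- volume$channels[[ch]]
    sc <- max(arr, 1e-12)
    scales[[ch]] <- sc
    pages <- vector("list", d[3] * d[4])
    for (k in seq_len(d[4])) for (z in seq_len(d[3])) {
      pages[[(k - 1) * d[3] + z]] <- pmin(arr[, , z, k] / sc, 1)
    }
    tiff::writeTIFF(pages, file.path(dir, paste0(name, "_", ch, ".tif")),
                    bits.per.sample = 16)
  }
  s <- volume$schedule
  sidecar <- list(
    dims = d, rate_hz = volume$rate_hz,
    channels = names(volume$channels), scales = scales,
    frame_times = as.vector(volume$frame_times),
    schedule = list(step_angle_deg = s$step_angle_deg, hold_s = s$hold_s,
                    transition_s = s$transition_s,
                    n_revolutions = s$n_revolutions,
                    polarizer_present = s$polarizer_present,
                    inactivity_s = s$inactivity_s),
    truth = truth
  )
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an imaging volume written by [write_imaging_volume()]
#'
#' @param dir Directory containing the files.
#' @param name Basename used when writing.
#' @return An `imaging_volume` (intensities rescaled to their original
#'   range up to 16-bit quantization), with the sidecar's `truth` attached
#'   as an attribute.
#' @export
read_imaging_volume <- function(dir, name = "volume") {
  sidecar <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                                 simplifyVector = TRUE)
  d <- sidecar$dims
  channels <- list()
  for (ch in sidecar$channels) {
    pages <- tiff::readTIFF(file.path(dir, paste0(name, "_", ch, ".tif")),
                            all = TRUE)
    arr <- array(0, dim = d)
    for (k in seq_len(d[4])) for (z in seq_len(d[3])) {
      arr[, , z, k] <- pages[[(k - 1) * d[3] + z]] * sidecar$scales[[ch]]
    }
    channels[[ch]] <- arr
  }
  sch <- do.call(make_schedule, sidecar$schedule)
  vol <- structure(list(
    channels = channels,
    frame_times = matrix(sidecar$frame_times, d[3], d[4]),
    rate_hz = sidecar$rate_hz, schedule = sch
  ), class = "imaging_volume")
  attr(vol, "truth") <- sidecar$truth
  vol
}

#' Write ROI masks as run-length-encoded JSON
#'
#' Lossless, text-only mask storage: per ROI the mask dimensions and the
#' run-length encoding of its column-major pixel vector.
#'
#' @param rois A `roi_set` or named list of logical masks.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_roi_masks <- function(rois, path) {
  if (inherits(rois, "roi_set")) rois <- rois$rois
  enc <- lapply(rois, function(m) {
    r <- rle(as.vector(m))
    list(dim = dim(m), lengths = r$lengths, values = as.integer(r$values))
  })
  jsonlite::write_json(enc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read ROI masks written by [write_roi_masks()]
#'
#' @param path JSON path.
#' @return Named list of logical masks.
#' @export
read_roi_masks <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(enc, function(e) {
    v <- inverse.rle(structure(list(lengths = e$lengths,
                                    values = as.logical(e$values)),
                               class = "rle"))
    matrix(v, e$dim[1], e$dim[2])
  })
}

#' Read a stimulus-event table from CSV
#'
#' Expects columns `event`, `time_s`, `value`; recognized events are the
#' schedule parameters (`step_angle_deg`, `hold_s`, `transition_s`,
#' `n_revolutions`, `polarizer_present`, `inactivity_s`) given as `value`
#' rows, from which the schedule is rebuilt.
#'
#' @param path CSV path.
#' @return A `stim_schedule`.
#' @export
read_schedule_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("event", "value") %in% names(tab)))
  get <- function(nm, default) {
    v <- tab$value[tab$event == nm]
    if (length(v)) as.numeric(v[1]) else default
  }
  make_schedule(
    step_angle_deg = get("step_angle_deg", 30),
    hold_s = get("hold_s", 4),
    transition_s = get("transition_s", 0.5),
    n_revolutions = get("n_revolutions", 2),
    polarizer_present = as.logical(get("polarizer_present", 1)),
    inactivity_s = get("inactivity_s", 10)
  )
}

#' Write a schedule as a stimulus-event CSV
#'
#' @param schedule A `stim_schedule`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "stim_schedule"))
  tab <- data.frame(
    event = c("step_angle_deg", "hold_s", "transition_s", "n_revolutions",
              "polarizer_present", "inactivity_s"),
    time_s = 0,
    value = c(schedule$step_angle_deg, schedule$hold_s,
              schedule$transition_s, schedule$n_revolutions,
              as.integer(schedule$polarizer_present),
              schedule$inactivity_s)
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
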