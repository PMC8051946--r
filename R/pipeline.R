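#' Run the polarization-tuning analysis pipeline end to end
#'
#' Orchestrates a full run: obtain a volume (synthetic, via
#' [render_volume()], or from files written by [write_imaging_volume()]),
#' register it on the structural channel, build the inactivity
#' projection, compute per-pixel tunings and PSI, partition regions,
#' derive the PSI threshold, and run the selected analyses. Writes
#' long-format CSV tables, and a JSON manifest carrying every seed and
#' threshold needed to reproduce the run byte-for-byte.
#'
#' @param config A list with elements:
#'   * `mode`: `"synthetic"` (default) or `"files"`;
#'   * `seed`: integer master seed (required);
#'   * `scene`, `schedule_args`, `shape`, `rate_hz`: synthetic-mode inputs
#'     (`scene` a [make_scene()], or `n_neurons` to build a
#'     [gradient_neurons()] scene);
#'   * `input_dir`, `input_name`: file-mode inputs;
#'   * `analyses`: subset of `c("tuning", "polarotopy", "population")`
#'     (default all);
#'   * `animal`, `recording`: identifiers stamped into the tables.
#' @param out_dir Output directory for tables and the manifest.
#' @return Invisibly, a list with the result tables (`pixel_tunings`,
#'   `region_summary`, `polarotopy` if run), the `manifest`, and the
#'   intermediate objects.
#' @export
run_polarization_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config), !is.null(config$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  analyses <- config$analyses %||% c("tuning", "polarotopy", "population")
  animal <- config$animal %||% "animal1"
  recording <- config$recording %||% "rec1"
  mode <- config$mode %||% "synthetic"
  if (mode == "synthetic") {
    schedule <- do.call(make_schedule, config$schedule_args %||% list())
    shape <- config$shape %||% c(48, 48, 1)
    rate_hz <- config$rate_hz %||% 2
    scene <- config$scene
    if (is.null(scene)) {
      neurons <- gradient_neurons(config$n_neurons %||% 10, shape,
                                  seed = seed)
      scene <- make_scene(neurons, noise_sd = config$noise_sd %||% 5)
    }
    rendered <- render_volume(scene, schedule, shape, rate_hz = rate_hz,
                              seed = seed)
    volume <- rendered$volume
    truth <- rendered$scene
  } else {
    volume <- read_imaging_volume(config$input_dir,
                                  config$input_name %||% "volume")
    schedule <- volume$schedule
    truth <- NULL
  }
  reg <- register_volume(volume)
  proj <- inactivity_projection(reg$volume, schedule)
  stages <- c("register_volume", "inactivity_projection")
  tunings <- NULL; region_summary <- NULL; threshold <- NA_real_
  pol <- NULL
  if (schedule$polarizer_present && "tuning" %in% analyses) {
    tunings <- pixel_tuning(proj, schedule)
    stages <- c(stages, "pixel_tuning")
    ## overall ROI: pixels clearly above the background level of the
    ## inactivity mean (synthetic surrogate for the hand-drawn mask)
    ref <- proj$inactivity_mean
    overall <- ref > stats::quantile(ref, 0.75)
    part <- region_partition(ref, overall)
    threshold <- psi_threshold(tunings$psi[as.vector(part$background) &
                                             !is.na(tunings$psi)])
    stages <- c(stages, "region_partition", "psi_threshold")
    region_summary <- tibble::tibble(
      animal = animal, recording = recording,
      region = c("overall", "neurons", "background"),
      n_px = c(sum(part$overall), sum(part$neurons), sum(part$background)),
      median_psi = c(
        stats::median(tunings$psi[as.vector(part$overall)], na.rm = TRUE),
        stats::median(tunings$psi[as.vector(part$neurons)], na.rm = TRUE),
        stats::median(tunings$psi[as.vector(part$background)], na.rm = TRUE))
    )
    tunings <- dplyr::mutate(tunings, animal = animal,
                             recording = recording,
                             above_threshold = !is.na(.data$psi) &
                               .data$psi >= threshold)
    utils::write.csv(tunings, file.path(out_dir, "pixel_tunings.csv"),
                     row.names = FALSE)
    utils::write.csv(region_summary,
                     file.path(out_dir, "region_summary.csv"),
                     row.names = FALSE)
    if ("polarotopy" %in% analyses) {
      sel <- tunings[tunings$above_threshold, ]
      if (nrow(sel) >= 4 && stats::sd(sel$col) > 0) {
        pol_data <- tibble::tibble(
          animal = animal, recording = recording, hemisphere = "right",
          position = normalize_positions(sel$col, sel$row, "horizontal"),
          aop_deg = sel$phi_deg, psi = sel$psi)
        pol <- polarotopy_analysis(pol_data,
                                   n_perm = config$n_perm %||% 1000,
                                   n_boot = config$n_boot %||% 1000,
                                   seed = seed + 10L)
        utils::write.csv(glance(pol), file.path(out_dir, "polarotopy.csv"),
                         row.names = FALSE)
        stages <- c(stages, "polarotopy_analysis")
      }
    }
    if ("population" %in% analyses) {
      in_roi <- as.vector(part$overall) & !is.na(tunings$psi) &
        !is.na(tunings$phi_deg)
      pv <- population_vector(tunings$phi_deg[in_roi],
                              tunings$psi[in_roi], basis = "pixel")
      utils::write.csv(dplyr::mutate(pv, animal = animal,
                                     recording = recording),
                       file.path(out_dir, "population_vector.csv"),
                       row.names = FALSE)
      stages <- c(stages, "population_vector")
    }
  } else if (!schedule$polarizer_present) {
    ## polarizer-removed control: per-pixel PSI only (no polarotopy)
    ctrl_sched <- schedule
    tunings <- control_pixel_psi(proj, ctrl_sched)
    ref <- proj$inactivity_mean
    overall <- ref > stats::quantile(ref, 0.75)
    part <- region_partition(ref, overall)
    region_summary <- tibble::tibble(
      animal = animal, recording = recording,
      region = c("neurons", "background"),
      n_px = c(sum(part$neurons), sum(part$background)),
      median_psi = c(
        stats::median(tunings$psi[as.vector(part$neurons)], na.rm = TRUE),
        stats::median(tunings$psi[as.vector(part$background)], na.rm = TRUE))
    )
    utils::write.csv(tunings, file.path(out_dir, "pixel_tunings.csv"),
                     row.names = FALSE)
    utils::write.csv(region_summary,
                     file.path(out_dir, "region_summary.csv"),
                     row.names = FALSE)
    stages <- c(stages, "control_pixel_psi", "region_partition")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("poltune")),
    mode = mode, seed = seed, analyses = analyses,
    animal = animal, recording = recording,
    psi_threshold = threshold,
    schedule = list(step_angle_deg = schedule$step_angle_deg,
                    hold_s = schedule$hold_s,
                    transition_s = schedule$transition_s,
                    n_revolutions = schedule$n_revolutions,
                    polarizer_present = schedule$polarizer_present),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pixel_tunings = tunings, region_summary = region_summary,
                 polarotopy = pol, manifest = manifest,
                 projection = proj, threshold = threshold,
                 truth = truth))
}

#' Per-pixel PSI for a polarizer-removed control recording
#'
#' The control protocol rotates the same device with the polarizer
#' removed; the analysis is identical to the tuning analysis (per-device-
#' position averages, nominal angle labels from the device position), so
#' residual PSI quantifies modulation not caused by polarization.
#'
#' @param projection An `inactivity_projection` of the control recording.
#' @param schedule The polarizer-removed `stim_schedule`.
#' @return The [pixel_tuning()] tibble computed with nominal angle labels.
#' @export
control_pixel_psi <- function(projection, schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  if (schedule$polarizer_present) {
    stop("control_pixel_psi expects a polarizer-removed schedule")
  }
  ## label positions with the nominal AoPs the device *would* present
  labeled <- schedule
  labeled$polarizer_present <- TRUE
  k <- labeled$positions$position - 1L
  labeled$positions$aop_deg <- wrap_axial(k * labeled$step_angle_deg)
  pixel_tuning(projection, labeled)
}
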