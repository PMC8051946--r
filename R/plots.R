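#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

map_to_long <- function(m, value_name) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}

#' Plot a polarization tuning map
#'
#' Above-threshold pixels are colored by preferred AoP on a 180-degree
#' periodic hue wheel; all other pixels show normalized inactivity-mean
#' intensity in grayscale.
#'
#' @param object A [tuning_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tuning_map <- function(object, ...) {
  hue <- map_to_long(object$hue_deg, "aop_deg")
  gray <- map_to_long(object$gray, "intensity")
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = gray[!is.na(gray$intensity), ],
                         ggplot2::aes(x = .data$col, y = .data$row,
                                      alpha = .data$intensity),
                         fill = "grey30") +
    ggplot2::geom_raster(data = hue[!is.na(hue$aop_deg), ],
                         ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = (.data$aop_deg + 90) %% 180)) +
    ggplot2::scale_fill_gradientn(
      colours = grDevices::hcl.colors(13, "Spectral"),
      limits = c(0, 180), name = "preferred AoP (deg)") +
    ggplot2::scale_alpha_continuous(range = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Tuning map (PSI threshold %.2f)",
                                  object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot an area-true polar histogram
#'
#' Wedge radii encode the square root of each bin's probability, so wedge
#' area is proportional to probability. The axial distribution is drawn
#' on a half-turn mirrored to the full circle.
#'
#' @param object A [polar_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.polar_histogram <- function(object, ...) {
  d <- rbind(
    tibble::as_tibble(object),
    dplyr::mutate(tibble::as_tibble(object),
                  bin_lo = .data$bin_lo + 180,
                  bin_hi = .data$bin_hi + 180,
                  bin_mid = .data$bin_mid + 180)
  )
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$bin_lo,
                                    xmax = .data$bin_hi,
                                    ymin = 0, ymax = .data$r)) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-90, 270),
                                breaks = seq(-90, 240, 30)) +
    ggplot2::labs(x = "preferred AoP (deg)", y = NULL,
                  title = "Preferred-angle distribution (area-true)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a polarotopy scatter with regression lines
#'
#' Subsampled pooled scatter of preferred AoP against normalized
#' position, with the pooled circular-linear regression line (drawn over
#' its axial wrap).
#'
#' @param object A [polarotopy_analysis()] result.
#' @param color `"aop"` (default) or `"psi"` point coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.polarotopy <- function(object, color = c("aop", "psi"), ...) {
  color <- match.arg(color)
  d <- object$scatter
  fit <- object$pooled
  xs <- seq(0, 1, length.out = 200)
  line <- tibble::tibble(
    x = xs,
    aop = wrap_axial(fit$phase_deg + 180 * fit$slope_cycles * xs)
  )
  ## break the line at wrap points so it is not drawn across jumps
  line$grp <- cumsum(c(0, abs(diff(line$aop)) > 90))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                       y = .data$aop_deg))
  p <- if (color == "psi" && "psi" %in% names(d)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$psi), size = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = (.data$aop_deg + 90) %% 180),
                            size = 0.8, show.legend = FALSE)
  }
  p +
    ggplot2::geom_line(data = line,
                       ggplot2::aes(x = .data$x, y = .data$aop,
                                    group = .data$grp),
                       linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(-90, 90),
                                breaks = seq(-90, 90, 30)) +
    ggplot2::labs(x = "normalized position", y = "preferred AoP (deg)",
                  subtitle = sprintf("pooled rho = %.2f, p = %.3g",
                                     fit$rho, fit$p_perm %||% NA)) +
    ggplot2::theme_minimal()
}

#' Plot an aligned average tuning curve
#'
#' @param curve The tibble returned by [aligned_average_curve()].
#' @return A ggplot.
#' @export
plot_tuning_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$offset_deg, y = .data$dff)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "angle from preferred (deg)",
                  y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
}

#' Plot a pairing-correlation profile
#'
#' Mean Fisher-z cross-correlation for each of the 8 wrapped left/right
#' pairing schemes.
#'
#' @param profile The `profile` tibble from [best_pairing()].
#' @return A ggplot.
#' @export
plot_pairing_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$shift,
                                        y = .data$mean_rho)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 0:7) +
    ggplot2::labs(x = "pairing-scheme shift", y = "mean correlation") +
    ggplot2::theme_minimal()
}
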