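#' Wrap an angle of polarization into the axial range
#'
#' Angles of polarization (AoP) are axial quantities defined modulo 180
#' degrees. The package-wide convention places them in `[-90, 90)`, with 0
#' degrees vertical, viewed from an external viewpoint toward the fly.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Angles wrapped to `[-90, 90)`.
#' @export
#' @examples
#' wrap_axial(c(0, 90, 120, 270))
wrap_axial <- function(deg) {
  ((deg + 90) %% 180) - 90
}

#' Signed and absolute axial angular differences
#'
#' The signed axial difference `a - b` wrapped to `[-90, 90)`; the absolute
#' axial distance lies in `[0, 90]`.
#'
#' @param a,b Angles in degrees (axial, mod 180).
#' @return Difference(s) in degrees.
#' @export
axial_diff <- function(a, b) {
  wrap_axial(a - b)
}

#' @rdname axial_diff
#' @export
axial_dist <- function(a, b) {
  d <- abs(axial_diff(a, b))
  pmin(d, 180 - d)
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Min-max normalize to the unit interval
#'
#' @param x Numeric vector or matrix.
#' @param na_flat Value used when `x` has zero range (degenerate input);
#'   the result is flagged with attribute `flat = TRUE`.
#' @return Object of the same shape scaled to `[0, 1]`.
#' @keywords internal
minmax_norm <- function(x, na_flat = 0) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    out <- x
    out[] <- na_flat
    attr(out, "flat") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  attr(out, "flat") <- FALSE
  out
}

## deterministic scan order: row-major, origin top-left (row, then column)
scan_order <- function(nrow, ncol) {
  order(rep(seq_len(nrow), times = ncol) * ncol + rep(seq_len(ncol), each = nrow))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
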