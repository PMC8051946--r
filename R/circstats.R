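#' Weighted axial mean resultant vector
#'
#' Computes the mean angle and resultant length of axial (180-degree
#' periodic) data by the doubling method: angles are doubled, the weighted
#' first trigonometric moment is taken, and the resultant angle is halved.
#' When the data are grouped at a fixed angular spacing (as with a stepped
#' polarizer), the resultant length is multiplied by the grouped-data
#' correction factor \eqn{c = (\delta/2)/\sin(\delta/2)} with
#' \eqn{\delta} the doubled spacing in radians, capped at 1.
#'
#' @param angles_deg Angles in degrees, interpreted modulo 180.
#' @param weights Optional non-negative weights (e.g. fluorescence or PSI);
#'   defaults to equal weights. Must sum to a positive value.
#' @param grouping_deg Optional angular spacing of the (axial) grouping in
#'   degrees, e.g. 30 for a 30-degree stepped stimulus. `NULL` for ungrouped.
#' @return A list with `mean_deg` (in `[-90, 90)`, `NA` when the resultant
#'   vanishes), `R` (resultant length in `[0, 1]` after correction), and
#'   `defined` (`FALSE` when `R` is numerically zero).
#' @export
#' @examples
#' axial_mean(c(0, 30, 60, 90, 120, 150))$R          # uniform: 0
#' axial_mean(c(10, 10, 10))                          # concentrated: R = 1
#' axial_mean(c(0, 45, 90, 135), weights = c(2, 1, 0, 1))
axial_mean <- function(angles_deg, weights = NULL, grouping_deg = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  stopifnot(length(weights) == length(angles_deg))
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- sum(weights)
  if (!(w > 0)) stop("total weight must be positive")
  psi <- deg2rad(2 * angles_deg)
  C <- sum(weights * cos(psi))
  S <- sum(weights * sin(psi))
  R <- sqrt(C^2 + S^2) / w
  if (!is.null(grouping_deg)) {
    R <- min(1, R * grouping_correction(grouping_deg))
  }
  defined <- R > sqrt(.Machine$double.eps)
  mean_deg <- if (defined) wrap_axial(rad2deg(atan2(S, C) / 2)) else NA_real_
  list(mean_deg = mean_deg, R = R, defined = defined)
}

#' Grouped-data correction factor for axial resultant lengths
#'
#' For axial data grouped at spacing `grouping_deg` the doubled angles are
#' grouped at \eqn{\delta = 2 \cdot} `grouping_deg`; the standard correction
#' multiplies the resultant length by \eqn{(\delta/2)/\sin(\delta/2)}.
#'
#' @inheritParams axial_mean
#' @return The correction factor (>= 1).
#' @export
#' @examples
#' grouping_correction(30)  # (pi/6)/sin(pi/6) = 1.0472
grouping_correction <- function(grouping_deg) {
  stopifnot(grouping_deg > 0, grouping_deg <= 90)
  half_delta <- deg2rad(2 * grouping_deg) / 2
  half_delta / sin(half_delta)
}

#' Rayleigh test of uniformity for axial data
#'
#' Tests the null hypothesis of circular uniformity on doubled angles using
#' the classical series approximation
#' \eqn{p = e^{-Z}[1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]}
#' with \eqn{Z = nR^2}.
#'
#' Weights are deliberately unsupported: the sampling theory assumes unit
#' observations, so callers must pass individual angle observations.
#'
#' @param angles_deg Angles in degrees; `n >= 4` required.
#' @param axial If `TRUE` (default) angles are doubled before testing
#'   (180-degree periodic data).
#' @return A list with `R`, `Z` and `p` (clamped to `(0, 1]`).
#' @export
rayleigh_test <- function(angles_deg, axial = TRUE) {
  n <- length(angles_deg)
  if (n < 4) stop("rayleigh_test requires at least 4 observations")
  th <- deg2rad(if (axial) 2 * angles_deg else angles_deg)
  C <- sum(cos(th)); S <- sum(sin(th))
  R <- sqrt(C^2 + S^2) / n
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(R = R, Z = Z, p = min(max(p, .Machine$double.xmin), 1))
}

#' Confidence interval for an axial mean angle
#'
#' A normal-approximation 95% CI for the axial mean direction, from the
#' circular dispersion of the doubled angles. The interval is reported as
#' not available (`NA`) when the Rayleigh test on the same sample is not
#' significant at `alpha_gate`, since the mean direction is then
#' uninterpretable.
#'
#' @inheritParams rayleigh_test
#' @param conf Confidence level (default 0.95).
#' @param alpha_gate Rayleigh-test significance gate (default 0.05).
#' @return A list with `mean_deg`, `lower_deg`, `upper_deg`, `halfwidth_deg`,
#'   and `available`.
#' @export
axial_mean_ci <- function(angles_deg, conf = 0.95, alpha_gate = 0.05) {
  n <- length(angles_deg)
  am <- axial_mean(angles_deg)
  rt <- rayleigh_test(angles_deg)
  th <- deg2rad(2 * angles_deg)
  mu2 <- deg2rad(2 * (if (is.na(am$mean_deg)) 0 else am$mean_deg))
  R1 <- rt$R
  ## second central trigonometric moment of the doubled angles
  R2 <- sqrt(sum(cos(2 * (th - mu2)))^2 + sum(sin(2 * (th - mu2)))^2) / n
  if (rt$p >= alpha_gate || !am$defined || R1 <= 0) {
    return(list(mean_deg = am$mean_deg, lower_deg = NA_real_,
                upper_deg = NA_real_, halfwidth_deg = NA_real_,
                available = FALSE))
  }
  disp <- (1 - R2) / (2 * R1^2)
  se <- sqrt(disp / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  arg <- z * se
  if (arg >= 1) {
    hw <- NA_real_
    avail <- FALSE
  } else {
    hw <- rad2deg(asin(arg)) / 2   # halved back to the axial scale
    avail <- TRUE
  }
  list(mean_deg = am$mean_deg,
       lower_deg = if (avail) wrap_axial(am$mean_deg - hw) else NA_real_,
       upper_deg = if (avail) wrap_axial(am$mean_deg + hw) else NA_real_,
       halfwidth_deg = hw, available = avail)
}

#' Circular-circular correlation for axial data
#'
#' The T-linear circular correlation coefficient computed on doubled angles:
#' \deqn{\rho = \frac{\sum \sin(\alpha_i - \bar\alpha)\sin(\beta_i - \bar\beta)}
#'   {\sqrt{\sum \sin^2(\alpha_i - \bar\alpha) \sum \sin^2(\beta_i - \bar\beta)}}}
#' where the means are circular means of the doubled angles.
#'
#' @param a_deg,b_deg Equal-length angle vectors in degrees (axial).
#' @param axial Double the angles first (default `TRUE`).
#' @return The correlation coefficient in `[-1, 1]`, or `NA` (with a
#'   warning) if either sample has zero circular variance.
#' @export
circ_circ_corr <- function(a_deg, b_deg, axial = TRUE) {
  stopifnot(length(a_deg) == length(b_deg))
  if (length(a_deg) < 4) stop("circ_circ_corr requires at least 4 pairs")
  k <- if (axial) 2 else 1
  al <- deg2rad(k * a_deg); be <- deg2rad(k * b_deg)
  abar <- atan2(sum(sin(al)), sum(cos(al)))
  bbar <- atan2(sum(sin(be)), sum(cos(be)))
  sa <- sin(al - abar); sb <- sin(be - bbar)
  n <- length(sa)
  if (sum(sa^2) < n * 1e-20 || sum(sb^2) < n * 1e-20) {
    warning("zero circular variance in at least one sample; correlation undefined")
    return(NA_real_)
  }
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den <= 0) {
    warning("zero circular variance in at least one sample; correlation undefined")
    return(NA_real_)
  }
  sum(sa * sb) / den
}

#' Fisher-z mean of correlation coefficients
#'
#' Back-transformed mean of `atanh(rho)`. Coefficients at exactly +/-1 are
#' clipped to `1 - eps` in magnitude (with a warning) before transforming.
#'
#' @param rhos Correlation coefficients.
#' @param eps Clip margin for `|rho| = 1` (default `1e-7`).
#' @param na_rm Drop `NA` values first.
#' @return The mean correlation coefficient.
#' @export
#' @examples
#' fisher_mean(c(0.5, 0.5))
#' fisher_mean(c(0, 0.9))
fisher_mean <- function(rhos, eps = 1e-7, na_rm = TRUE) {
  if (na_rm) rhos <- rhos[!is.na(rhos)]
  if (length(rhos) == 0) stop("no correlation coefficients supplied")
  if (any(abs(rhos) > 1)) stop("|rho| > 1 is not a correlation coefficient")
  clipped <- abs(rhos) >= 1
  if (any(clipped)) {
    warning(sum(clipped), " coefficient(s) at |rho| = 1 clipped by eps before Fisher transform")
    rhos[clipped] <- sign(rhos[clipped]) * (1 - eps)
  }
  tanh(mean(atanh(rhos)))
}

## resultant length of (psi - 2*pi*a*x) as a function of slope a (cycles/unit)
circlin_resultant <- function(a, x, psi) {
  ph <- psi - 2 * pi * a * x
  sqrt(sum(cos(ph))^2 + sum(sin(ph))^2) / length(ph)
}

## golden-section maximisation of the resultant over a bracket
golden_max <- function(f, lo, hi, tol = 1e-8) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}

#' Circular-linear regression of axial angles on position
#'
#' Fits the polarotopy model: doubled preferred angles \eqn{\psi = 2\theta}
#' are regressed on normalized position `x` by choosing the slope `a` (in
#' cycles of doubled angle per unit position) that maximizes the resultant
#' length of \eqn{\psi - 2\pi a x}, searched on a bounded grid with
#' golden-section refinement. The phase offset is the resultant angle at the
#' optimum, and the correlation coefficient is the circular-circular
#' correlation between the observed doubled angles and the fitted phases
#' \eqn{2\pi a x}, with the sign taken from the slope direction.
#'
#' @param x Normalized positions in `[0, 1]`.
#' @param angles_deg Axial angles in degrees.
#' @param slope_range Search bounds for the slope in cycles per unit
#'   position (default `c(-4, 4)`).
#' @param n_grid Number of grid points over `slope_range` (default 1601).
#' @param refine Apply golden-section refinement around the best grid point
#'   (default `TRUE`).
#' @return An object of class `circlin_fit`: a list with `slope_cycles`,
#'   `phase_deg` (AoP intercept at `x = 0`, in `[-90, 90)`), `rho`,
#'   `resultant`, `n`, plus the inputs.
#' @seealso [circ_lin_perm_test()] for the permutation p-value,
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
circ_lin_fit <- function(x, angles_deg, slope_range = c(-4, 4),
                         n_grid = 1601, refine = TRUE) {
  n <- length(x)
  stopifnot(length(angles_deg) == n)
  if (n < 4) stop("circ_lin_fit requires at least 4 points")
  if (stats::sd(x) == 0) stop("positions are degenerate (all equal)")
  psi <- deg2rad(2 * angles_deg)
  grid <- seq(slope_range[1], slope_range[2], length.out = n_grid)
  Rg <- vapply(grid, circlin_resultant, numeric(1), x = x, psi = psi)
  i <- which.max(Rg)
  a <- grid[i]
  if (refine) {
    lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
    a <- golden_max(function(s) circlin_resultant(s, x, psi), lo, hi)
    if (circlin_resultant(a, x, psi) < Rg[i]) a <- grid[i]
  }
  ph <- psi - 2 * pi * a * x
  theta0 <- atan2(sum(sin(ph)), sum(cos(ph)))
  fitted <- rad2deg((2 * pi * a * x + theta0) %% (2 * pi)) / 2
  rho <- circlin_rho(x, angles_deg, a)
  structure(list(slope_cycles = a,
                 phase_deg = wrap_axial(rad2deg(theta0) / 2),
                 rho = rho,
                 resultant = circlin_resultant(a, x, psi),
                 fitted_deg = wrap_axial(fitted),
                 n = n, x = x, angles_deg = angles_deg,
                 slope_range = slope_range, n_grid = n_grid),
            class = "circlin_fit")
}

## signed correlation between observed doubled angles and fitted phases
circlin_rho <- function(x, angles_deg, a) {
  if (a == 0) return(0)
  fitted_deg <- rad2deg(2 * pi * a * x) / 2   # axial scale
  r <- suppressWarnings(circ_circ_corr(angles_deg, fitted_deg))
  if (is.na(r)) return(0)
  sign(a) * min(abs(r), 1)
}

#' @export
print.circlin_fit <- function(x, ...) {
  cat("Circular-linear fit (axial angles vs normalized position)\n")
  cat(sprintf("  n = %d, slope = %.4f cycles/unit, phase = %.2f deg\n",
              x$n, x$slope_cycles, x$phase_deg))
  cat(sprintf("  rho = %.4f, resultant = %.4f", x$rho, x$resultant))
  if (!is.null(x$p_perm)) cat(sprintf(", permutation p = %.3g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' Permutation test for the circular-linear correlation
#'
#' Shuffles the pairing of positions and angles `n_perm` times, refits the
#' slope on the same bounded grid for every shuffle, and reports the
#' upper-bound p-value \eqn{p = (b + 1)/(n_{perm} + 1)} where `b` counts
#' shuffles with `|rho|` at least as large as observed. For exchangeability
#' the observed statistic used in the comparison is recomputed with the
#' identical grid-only procedure applied to the shuffles.
#'
#' @inheritParams circ_lin_fit
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for reproducibility.
#' @return A list with `p_perm`, `rho_obs` (grid-only statistic), `b`,
#'   and `n_perm`.
#' @export
circ_lin_perm_test <- function(x, angles_deg, n_perm = 10000, seed = NULL,
                               slope_range = c(-4, 4), n_grid = 1601) {
  n <- length(x)
  stopifnot(length(angles_deg) == n)
  if (n < 4) stop("at least 4 points required")
  if (!is.null(seed)) set.seed(seed)
  psi <- deg2rad(2 * angles_deg)
  grid <- seq(slope_range[1], slope_range[2], length.out = n_grid)
  ## E[g, j] = exp(-i 2 pi a_g x_j); R(a_g) = |E %*% exp(i psi)| / n
  E <- exp(-1i * 2 * pi * outer(grid, x))
  stat <- function(psi_vec, angles_vec) {
    Rg <- Mod(E %*% exp(1i * psi_vec)) / n
    a <- grid[which.max(Rg)]
    circlin_rho(x, angles_vec, a)
  }
  rho_obs <- stat(psi, angles_deg)
  ## permutations in chunks to bound memory
  b <- 0L
  chunk <- max(1L, min(n_perm, as.integer(2e7 / n_grid)))
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    P <- matrix(0i, n, m)
    idx <- replicate(m, sample.int(n))
    for (j in seq_len(m)) P[, j] <- exp(1i * psi[idx[, j]])
    Rg <- Mod(E %*% P) / n
    best <- grid[max.col(t(Rg), ties.method = "first")]
    for (j in seq_len(m)) {
      r <- circlin_rho(x, angles_deg[idx[, j]], best[j])
      if (abs(r) >= abs(rho_obs)) b <- b + 1L
    }
    done <- done + m
  }
  list(p_perm = (b + 1) / (n_perm + 1), rho_obs = rho_obs, b = b,
       n_perm = n_perm)
}

#' Hierarchical bootstrap confidence interval for a mean correlation
#'
#' Two-stage bootstrap for nested data (recordings within flies): each
#' replicate resamples flies with replacement, then resamples each chosen
#' fly's recordings with replacement, and computes the Fisher-z mean of the
#' sampled coefficients. The interval is bias-corrected and accelerated
#' (BCa), with the acceleration estimated by jackknifing over flies.
#'
#' @param rho_by_fly A list, one element per fly, each a numeric vector of
#'   per-recording correlation coefficients. At least 2 flies required.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return An object of class `bootstrap_ci`: list with `point` (Fisher-z
#'   mean of all recordings), `lower`, `upper`, `n_boot`, `n_resampled`
#'   (replicates that had to be redrawn because their mean was undefined),
#'   and `seed`.
#' @export
hier_bootstrap_ci <- function(rho_by_fly, n_boot = 10000, conf = 0.95,
                              seed = NULL) {
  stopifnot(is.list(rho_by_fly))
  rho_by_fly <- lapply(rho_by_fly, function(v) v[!is.na(v)])
  rho_by_fly <- rho_by_fly[lengths(rho_by_fly) > 0]
  n_fly <- length(rho_by_fly)
  if (n_fly < 2) stop("hierarchical bootstrap requires at least 2 flies")
  if (!is.null(seed)) set.seed(seed)
  point <- fisher_mean(unlist(rho_by_fly))
  one_rep <- function() {
    flies <- sample.int(n_fly, n_fly, replace = TRUE)
    vals <- unlist(lapply(rho_by_fly[flies], function(v) {
      v[sample.int(length(v), length(v), replace = TRUE)]
    }))
    suppressWarnings(fisher_mean(vals))
  }
  boot <- numeric(n_boot)
  n_resampled <- 0L
  for (i in seq_len(n_boot)) {
    v <- one_rep()
    while (!is.finite(v)) { n_resampled <- n_resampled + 1L; v <- one_rep() }
    boot[i] <- v
  }
  if (stats::sd(boot) == 0) {
    out <- list(point = point, lower = boot[1], upper = boot[1],
                n_boot = n_boot, n_resampled = n_resampled, seed = seed,
                conf = conf)
    class(out) <- "bootstrap_ci"
    return(out)
  }
  ## BCa: bias correction from the replicate distribution, acceleration
  ## from a delete-one-fly jackknife
  prop_less <- mean(boot < point)
  prop_less <- min(max(prop_less, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- stats::qnorm(prop_less)
  jack <- vapply(seq_len(n_fly), function(i) {
    fisher_mean(unlist(rho_by_fly[-i]))
  }, numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom > 0) sum((jm - jack)^3) / (6 * denom) else 0
  alpha <- (1 - conf) / 2
  zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
  p_lo <- stats::pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
  p_hi <- stats::pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
  qs <- stats::quantile(boot, c(p_lo, p_hi), names = FALSE, type = 7)
  out <- list(point = point, lower = qs[1], upper = qs[2], n_boot = n_boot,
              n_resampled = n_resampled, seed = seed, conf = conf)
  class(out) <- "bootstrap_ci"
  out
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("Hierarchical bootstrap %g%% CI: %.4f [%.4f, %.4f] (%d replicates)\n",
              100 * x$conf, x$point, x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.circlin_fit <- function(x, ...) {
  tibble::tibble(term = c("slope_cycles", "phase_deg", "rho"),
                 estimate = c(x$slope_cycles, x$phase_deg, x$rho))
}

#' @export
glance.circlin_fit <- function(x, ...) {
  tibble::tibble(slope_cycles = x$slope_cycles, phase_deg = x$phase_deg,
                 rho = x$rho, resultant = x$resultant, n = x$n,
                 p_perm = x$p_perm %||% NA_real_)
}
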