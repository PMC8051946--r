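# fixtures are generated in code; nothing is read from disk

default_schedule <- function(...) make_schedule(...)

# smooth multi-blob reference image for registration tests
gauss_blob_image <- function(ny = 64, nx = 64) {
  g <- function(cy, cx, s) {
    d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+")
    exp(-d2 / (2 * s^2))
  }
  10 + 100 * g(20, 30, 4) + 80 * g(40, 45, 3) + 60 * g(50, 15, 5)
}

# circular mask around a point
disc_mask <- function(ny, nx, cy, cx, r) {
  outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+") <= r^2
}

# single-neuron scene for end-to-end checks
one_neuron_scene <- function(phi_deg = 30, A = 1, baseline = 100,
                             background = 5, noise_sd = 0, tau_s = 0,
                             motion = NULL) {
  make_scene(
    tibble::tibble(x = 24, y = 24, z = 1, radius_px = 3,
                   phi_deg = phi_deg, A = A, baseline = baseline),
    background = background, noise_sd = noise_sd, motion = motion,
    tau_s = tau_s)
}

# which schedule position (hold) covers time t, NA during gaps
position_at_test <- function(s, t) {
  p <- s$positions
  hit <- which(t >= p$t_on & t < p$t_off)
  if (length(hit)) hit[1] else NA_integer_
}

# brute-force doubled-angle trig sums: the independent oracle for the
# axial statistics
oracle_axial <- function(angles_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  th <- 2 * angles_deg * pi / 180
  C <- 0; S <- 0
  for (i in seq_along(th)) {
    C <- C + weights[i] * cos(th[i])
    S <- S + weights[i] * sin(th[i])
  }
  list(mean_deg = ((atan2(S, C) / 2 * 180 / pi + 90) %% 180) - 90,
       R = sqrt(C^2 + S^2) / sum(weights))
}

oracle_circ_circ <- function(a_deg, b_deg) {
  al <- 2 * a_deg * pi / 180; be <- 2 * b_deg * pi / 180
  abar <- atan2(sum(sin(al)), sum(cos(al)))
  bbar <- atan2(sum(sin(be)), sum(cos(be)))
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(al)) {
    num <- num + sin(al[i] - abar) * sin(be[i] - bbar)
    da <- da + sin(al[i] - abar)^2
    db <- db + sin(be[i] - bbar)^2
  }
  num / sqrt(da * db)
}
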