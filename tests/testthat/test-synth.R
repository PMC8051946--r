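test_that("schedule arithmetic follows the stepped-polarizer protocol", {
  s <- make_schedule(30, 4.0, 0.5, 2, polarizer_present = TRUE)
  expect_equal(nrow(s$positions), 24)
  expect_equal(sum(s$positions$revolution == 1), 12)
  expect_equal(length(aop_levels(s)), 6)
  # total stimulus duration 24 x 4.5 s; AoP period 6 x 4.5 s
  stim <- s$light_events$time_s[2] - s$light_events$time_s[1]
  expect_equal(stim, 24 * 4.5)
  expect_equal(aop_period_s(s), 27)
  expect_equal(phase_lock_window_s(s), 2)
  # AoP of position k is (k * step) mod 180
  k <- s$positions$position - 1
  expect_equal(s$positions$aop_deg, wrap_axial(k * 30))
  # positions are ordered and non-overlapping
  expect_true(all(diff(s$positions$t_on) > 0))
  expect_true(all(s$positions$t_off[-24] <= s$positions$t_on[-1]))
  # inactivity windows bracket the stimulus
  expect_equal(nrow(s$inactivity_windows), 2)
})

test_that("schedule arithmetic holds across step angles and rejects bad ones", {
  for (step in c(15, 30, 45, 90)) {
    s <- make_schedule(step, 4, 0, 1)
    expect_equal(nrow(s$positions) * step, 360)
    expect_equal(length(aop_levels(s)), 180 / step)
  }
  s90 <- make_schedule(90, 4.0, 0.0, 1)
  expect_equal(nrow(s90$positions), 4)
  expect_equal(length(aop_levels(s90)), 2)
  expect_error(make_schedule(step_angle_deg = 70), "divisor")
  expect_error(make_schedule(hold_s = 0), "hold_s")
})

test_that("hold jitter stays in the protocol band and is seeded", {
  s1 <- make_schedule(hold_jitter = TRUE, seed = 4)
  s2 <- make_schedule(hold_jitter = TRUE, seed = 4)
  holds <- s1$positions$t_off - s1$positions$t_on
  expect_true(all(holds >= 4 & holds <= 4.5))
  expect_gt(stats::sd(holds), 0)
  expect_identical(s1$positions, s2$positions)
})

test_that("response model matches its closed form during holds", {
  s <- make_schedule(30, 4, 0.5, 2)
  # A = 0: constant at B regardless of angle
  tr0 <- simulate_response(s, phi_deg = 57, A = 0, B = 3, tau_s = 0)
  expect_true(all(abs(tr0$mu - 3) < 1e-12))
  # orthogonal angle at full modulation: level 0
  tr <- simulate_response(s, phi_deg = 0, A = 1, B = 1, tau_s = 0)
  mid <- s$positions$t_on + 2   # mid-hold samples
  lev <- tr$mu[match(TRUE, tr$time_s >= mid[4]) ]  # position 4 = 90 deg
  expect_equal(lev, 1 + cos(2 * pi / 2), tolerance = 1e-9)
  # closed form at every hold midpoint
  for (i in seq_len(nrow(s$positions))) {
    want <- 1 + cos(2 * (s$positions$aop_deg[i] - 0) * pi / 180)
    got <- tr$mu[which(tr$time_s >= mid[i])[1]]
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("response model is axially symmetric and handles unpolarized light", {
  s <- make_schedule()
  a <- simulate_response(s, phi_deg = 20, A = 0.7, B = 2, tau_s = 1)
  b <- simulate_response(s, phi_deg = 200, A = 0.7, B = 2, tau_s = 1)
  expect_equal(a$mu, b$mu, tolerance = 1e-12)
  # polarizer removed: suppression to B(1 - A) during light-on
  ctrl <- make_schedule(n_revolutions = 1, polarizer_present = FALSE)
  tr <- simulate_response(ctrl, phi_deg = 0, A = 0.5, B = 2,
                          unpolarized_sign = -1, tau_s = 0)
  during <- tr$time_s >= ctrl$positions$t_on[2] &
    tr$time_s < ctrl$positions$t_off[2]
  expect_true(all(abs(tr$mu[during] - 1) < 1e-9))
  inact <- tr$time_s < 5
  expect_true(all(abs(tr$mu[inact] - 2) < 1e-9))
  expect_error(simulate_response(s, 0, A = 1.5, B = 1), "modulation depth")
  expect_error(simulate_response(s, 0, A = 0.5, B = 0), "baseline")
})

test_that("rendering conserves footprint-weighted trace sums frame by frame", {
  s <- make_schedule(90, 2, 0, 1, inactivity_s = 4)
  scene <- one_neuron_scene(phi_deg = 45, background = 2)
  rv <- render_volume(scene, s, c(48, 48, 1), rate_hz = 2, seed = 1)
  act <- rv$volume$channels$activity
  trace <- rv$scene$neurons$trace[[1]]
  fsum <- rv$scene$neurons$footprint_sum[1]
  nt <- dim(act)[4]
  for (k in seq(1, nt, by = 7)) {
    expect_equal(sum(act[, , 1, k]), 2 * 48 * 48 + fsum * trace[k],
                 tolerance = 1e-9)
  }
  # single neuron, zero noise: centroid voxel equals background + trace
  expect_equal(act[24, 24, 1, ] - 2, trace, tolerance = 1e-9)
})

test_that("rendering is deterministic under a fixed seed", {
  s <- make_schedule(90, 2, 0, 1, inactivity_s = 4)
  scene <- one_neuron_scene(noise_sd = 5)
  a <- render_volume(scene, s, c(32, 32, 1), seed = 7)
  b <- render_volume(scene, s, c(32, 32, 1), seed = 7)
  expect_identical(a$volume$channels, b$volume$channels)
  c <- render_volume(scene, s, c(32, 32, 1), seed = 8)
  expect_false(identical(a$volume$channels$activity,
                         c$volume$channels$activity))
})

test_that("out-of-bounds footprints are rejected", {
  s <- make_schedule(90, 2, 0, 1, inactivity_s = 4)
  scene <- make_scene(tibble::tibble(x = 100, y = 5, z = 1, radius_px = 2,
                                     phi_deg = 0, A = 1, baseline = 10))
  expect_error(render_volume(scene, s, c(32, 32, 1)), "bounds")
})

test_that("noiseless traces recover the injected preferred angle end to end", {
  s <- make_schedule()
  for (phi in c(-67, -30, 0, 42, 88)) {
    tr <- simulate_response(s, phi_deg = phi, A = 0.8, B = 100, tau_s = 1)
    tc <- tuning_curve(tr$f, tr$time_s, s)
    pa <- preferred_aop(tc)
    expect_lt(axial_dist(pa$phi_deg, phi), 15)  # within step/2
  }
})

test_that("PB dataset wires right glomeruli to their left partners", {
  s <- make_schedule()
  pb <- make_pb_dataset(s, pairing_shift = 0, noise_sd = 0)
  pc <- pairing_correlation(pb, 0)
  expect_true(all(abs(pc$pairs$rho - 1) < 1e-12))
  # true pairs beat every non-matching scheme on phase-staggered tuning
  profile <- best_pairing(pb)$profile
  expect_true(all(profile$mean_rho[profile$shift != 0] <
                    profile$mean_rho[profile$shift == 0]))
})

test_that("independent white-noise glomeruli show no preferred pairing", {
  s <- make_schedule()
  set.seed(17)
  nt <- length(seq(0, s$duration_s, by = 0.1))
  means <- replicate(20, {
    traces <- matrix(rnorm(nt * 16), nt, 16)
    colnames(traces) <- c(paste0(1:8, "L"), paste0(1:8, "R"))
    mean(best_pairing(traces)$profile$mean_rho)
  })
  expect_lt(abs(mean(means)), 0.05)
})
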