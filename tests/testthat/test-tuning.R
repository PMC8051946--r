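deg2rad_test <- function(d) d * pi / 180

test_that("tuning curves average per position and pool per AoP", {
  s <- make_schedule()
  tt <- seq(0, s$duration_s, by = 0.1)
  # constant series: curve constant at all K angles
  tc <- tuning_curve(rep(3, length(tt)), tt, s)
  expect_equal(length(tc$angles_deg), 6)
  expect_true(all(abs(tc$F_m - 3) < 1e-12))
  # closed form of the generator without kernel: F_m = 1 + cos(2 theta)
  tr <- simulate_response(s, phi_deg = 0, A = 1, B = 1, tau_s = 0)
  tc2 <- tuning_curve(tr$f, tr$time_s, s)
  expect_equal(tc2$F_m, 1 + cos(2 * deg2rad_test(tc2$angles_deg)),
               tolerance = 1e-9)
  # per-AoP mean equals the mean of that AoP's per-presentation entries
  for (a in tc2$angles_deg) {
    pp <- tc2$per_presentation
    expect_equal(tc2$F_m[tc2$angles_deg == a],
                 mean(pp$f_mean[axial_dist(pp$aop_deg, a) < 1e-9]),
                 tolerance = 1e-12)
  }
})

test_that("per-AoP pooling averages all four presentations of two revolutions", {
  s <- make_schedule(90, 2, 0, 2, inactivity_s = 4)
  tt <- seq(0, s$duration_s, by = 0.1)
  # value depends on position index: v, w within rev 1; v2, w2 in rev 2
  vals <- c(10, 20, 30, 40, 50, 60, 70, 80)  # 8 positions
  f <- rep(0, length(tt))
  for (i in 1:8) {
    sel <- tt >= s$positions$t_on[i] & tt < s$positions$t_off[i]
    f[sel] <- vals[i]
  }
  f[f == 0] <- 1
  tc <- tuning_curve(f, tt, s)
  # AoP 0 is presented at positions 1, 3, 5, 7 (0/180 deg device, both revs)
  expect_equal(tc$F_m[tc$angles_deg == 0], mean(c(10, 30, 50, 70)))
  expect_equal(tc$F_m[tc$angles_deg == -90], mean(c(20, 40, 60, 80)))
})

test_that("preferred angle comes from the weighted axial resultant", {
  s <- make_schedule(45, 2, 0, 1, inactivity_s = 4)
  curve <- structure(list(
    angles_deg = c(0, 45, -90, -45), F_m = c(2, 1, 0, 1),
    per_presentation = tibble::tibble(
      position = 1:8, revolution = 1,
      device_angle_deg = seq(0, 315, 45),
      aop_deg = wrap_axial(seq(0, 315, 45)),
      t_on = seq(4, by = 2, length.out = 8), n_samples = 4,
      f_mean = rep(c(2, 1, 0, 1), 2)),
    step_angle_deg = 45), class = "tuning_curve")
  pa <- preferred_aop(curve)
  expect_equal(pa$phi_deg, 0)
  # uncorrected R = 0.5 by the direct doubled-angle sum oracle
  expect_equal(oracle_axial(curve$angles_deg, curve$F_m)$R, 0.5,
               tolerance = 1e-12)
  # grouping correction applied on top
  expect_equal(pa$R, min(1, 0.5 * grouping_correction(45)), tolerance = 1e-12)
  # flat curve: undefined angle, zero resultant
  flat <- curve; flat$F_m <- rep(2, 4)
  pf <- preferred_aop(flat)
  expect_false(pf$defined)
  expect_equal(pf$R, 0, tolerance = 1e-12)
  # axial invariance: +180 relabeling changes nothing
  shifted <- curve; shifted$angles_deg <- curve$angles_deg + 180
  ps <- preferred_aop(shifted)
  expect_equal(ps$phi_deg, pa$phi_deg)
  expect_equal(ps$R, pa$R, tolerance = 1e-12)
})

test_that("PSI attains its defining bounds and values", {
  s <- make_schedule()
  tt <- seq(0, s$duration_s, by = 0.1)
  # equal responses at all angles: PSI = 0
  tc_flat <- tuning_curve(rep(5, length(tt)), tt, s)
  expect_equal(psi(tc_flat, 0)$psi, 0)
  # zero orthogonal response: PSI = 1
  tr <- simulate_response(s, phi_deg = 0, A = 1, B = 1, tau_s = 0)
  tc <- tuning_curve(tr$f, tr$time_s, s)
  expect_equal(psi(tc, 0)$psi, 1, tolerance = 1e-9)
  # F_pref = 3, F_ortho = 1 -> 0.5
  f <- rep(1, length(tt))
  pref_pos <- which(axial_dist(s$positions$aop_deg, 0) < 1e-9)[1:2]
  for (i in pref_pos) {
    f[tt >= s$positions$t_on[i] & tt < s$positions$t_off[i]] <- 3
  }
  tc3 <- tuning_curve(f, tt, s)
  expect_equal(psi(tc3, 0)$psi, 0.5, tolerance = 1e-12)
})

test_that("PSI uses the first two presentations in time of the nearest AoP", {
  s <- make_schedule()
  tt <- seq(0, s$duration_s, by = 0.1)
  # revolution 2 responses differ; only revolution 1 enters PSI
  f <- rep(1, length(tt))
  pos0 <- which(axial_dist(s$positions$aop_deg, 0) < 1e-9)
  f[tt >= s$positions$t_on[pos0[1]] & tt < s$positions$t_off[pos0[1]]] <- 4
  f[tt >= s$positions$t_on[pos0[2]] & tt < s$positions$t_off[pos0[2]]] <- 2
  f[tt >= s$positions$t_on[pos0[3]] & tt < s$positions$t_off[pos0[3]]] <- 100
  tc <- tuning_curve(f, tt, s)
  res <- psi(tc, 0)
  expect_equal(res$f_pref, 3)   # mean(4, 2); the 100 in rev 2 is ignored
  expect_equal(res$psi, (3 - 1) / (3 + 1))
  # nearest-angle tie at phi = 15: earlier AoP (0 deg) wins
  expect_equal(psi(tc, 15)$aop_pref_deg, 0)
})

test_that("delta PSI subtracts the control mean and summarises per animal", {
  expect_equal(delta_psi(0.74, c(0.16, 0.16)), 0.58, tolerance = 1e-12)
  expect_equal(delta_psi(c(0.2, 0.3), c(0.2, 0.3)), c(-0.05, 0.05))
  expect_error(delta_psi(0.5, numeric(0)), "empty")
  d <- tibble::tibble(animal = rep(c("a", "b"), each = 3),
                      psi = c(0.7, 0.74, 0.8, 0.6, 0.65, 0.61))
  out <- delta_psi_summary(d, control_psi_values = c(0.1, 0.22))
  expect_equal(out$median_delta_psi, c(0.74 - 0.16, 0.61 - 0.16),
               tolerance = 1e-12)
  expect_equal(attr(out, "mean_of_medians"), mean(c(0.58, 0.45)),
               tolerance = 1e-12)
})

test_that("PSI threshold is mean + 1 sample SD of the reference", {
  expect_equal(psi_threshold(rep(0.25, 5)), 0.25)
  v <- c(0.1, 0.3)
  expect_equal(psi_threshold(v), mean(v) + stats::sd(v), tolerance = 1e-12)
  expect_error(psi_threshold(numeric(0)), "empty")
})

test_that("tuning maps put every pixel in exactly one layer", {
  phi <- matrix(runif(100, -90, 90), 10)
  psi_m <- matrix(runif(100), 10)
  ref <- matrix(runif(100, 0, 50), 10)
  roi <- matrix(FALSE, 10, 10); roi[3:8, 3:8] <- TRUE
  tm <- tuning_map(phi, psi_m, threshold = 0.5, roi, ref)
  expect_true(all(xor(is.na(tm$hue_deg), is.na(tm$gray))))
  expect_true(all(which(!is.na(tm$hue_deg)) %in% which(roi & psi_m >= 0.5)))
  # unreachable threshold: pure grayscale
  tm2 <- tuning_map(phi, psi_m, 1.01, roi, ref)
  expect_equal(sum(!is.na(tm2$hue_deg)), 0)
  # zero threshold, full-frame ROI: all colored
  tm3 <- tuning_map(phi, psi_m, 0, matrix(TRUE, 10, 10), ref)
  expect_equal(sum(!is.na(tm3$hue_deg)), 100)
})

test_that("Fourier interpolation is exact at the original samples", {
  set.seed(5)
  for (K in c(4, 6, 9, 12)) {
    y <- rnorm(K)
    up <- fourier_interp(y, 360)
    expect_equal(up[seq(1, 360, by = 360 / K)], y, tolerance = 1e-10)
  }
})

test_that("aligned average curves peak at zero offset and remove phase", {
  angles <- seq(-90, 60, by = 30)
  mk <- function(phi) 1 + 0.8 * cos(2 * (angles - phi) * pi / 180)
  F_m <- rbind(mk(0), mk(30), mk(-57))
  out <- aligned_average_curve(F_m, angles, phi_deg = c(0, 30, -57),
                               F0 = rep(1, 3))
  expect_equal(out$offset_deg[which.max(out$dff)], 0)
  # identical curves at different phases align to the same shape
  single <- aligned_average_curve(rbind(mk(10)), angles, 10, 1)
  double <- aligned_average_curve(rbind(mk(40)), angles, 40, 1)
  expect_equal(single$dff, double$dff, tolerance = 1e-9)
  # F0 = 0 pixels are excluded and counted
  both <- aligned_average_curve(F_m, angles, c(0, 30, -57), c(1, 0, 1))
  expect_equal(attr(both, "n_excluded"), 1)
})

test_that("activity difference maps separate modality-specific modulation", {
  ny <- 8; nx <- 8; nt <- 40
  base <- array(10, dim = c(ny, nx, nt))
  pol <- base; bar <- base
  pol[3, 3, ] <- 10 + 5 * sin(seq_len(nt))      # polarization-only pixel
  bar[6, 6, ] <- 10 + 5 * sin(seq_len(nt))      # bar-only pixel
  d <- activity_difference_map(pol, bar)
  expect_gt(d[3, 3], 0)
  expect_lt(d[6, 6], 0)
  # identical inputs: difference identically zero
  same <- activity_difference_map(pol, pol)
  expect_true(all(same == 0))
  # zero-variance maps are flagged, not NaN
  flat <- activity_difference_map(base, base)
  expect_true(attr(flat, "flat"))
  expect_true(all(is.finite(flat)))
})

test_that("per-pixel tuning agrees with the per-trace route", {
  s <- make_schedule()
  rv <- render_volume(one_neuron_scene(phi_deg = 30), s, c(48, 48, 1),
                      rate_hz = 2, seed = 3)
  proj <- inactivity_projection(rv$volume)
  pt <- pixel_tuning(proj)
  # centroid pixel: same answer as the explicit tuning_curve route
  f <- proj$intensity[24, 24, ]
  tt <- proj$frame_times[1, ]
  tc <- tuning_curve(f, tt, s)
  pa <- preferred_aop(tc)
  ps <- psi(tc, pa$phi_deg)
  i <- which(pt$row == 24 & pt$col == 24)
  expect_equal(pt$phi_deg[i], pa$phi_deg, tolerance = 1e-9)
  expect_equal(pt$R[i], pa$R, tolerance = 1e-9)
  expect_equal(pt$psi[i], ps$psi, tolerance = 1e-9)
  expect_lt(axial_dist(pt$phi_deg[i], 30), 15)
})

test_that("PSI increases with modulation depth on noiseless fixtures", {
  s <- make_schedule()
  psis <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), function(A) {
    tr <- simulate_response(s, phi_deg = 0, A = A, B = 100, tau_s = 0)
    tc <- tuning_curve(tr$f, tr$time_s, s)
    psi(tc, preferred_aop(tc)$phi_deg)$psi
  }, numeric(1))
  expect_true(all(diff(psis) > 0))
})
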