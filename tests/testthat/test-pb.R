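test_that("ring distance is symmetric and bounded by 4", {
  for (i in 1:8) for (j in 1:8) {
    expect_equal(ring_distance(i, j), ring_distance(j, i))
    expect_lte(ring_distance(i, j), 4)
    expect_gte(ring_distance(i, j), 0)
  }
  expect_equal(ring_distance(1, 8), 1)
  expect_equal(ring_distance(1, 5), 4)
})

test_that("pairing correlation is exact for duplicated and negated partners", {
  s <- make_schedule()
  pb <- make_pb_dataset(s, pairing_shift = 2, noise_sd = 0)
  pc <- pairing_correlation(pb, 2)
  expect_true(all(abs(pc$pairs$rho - 1) < 1e-12))
  # negated partners: coefficient -1
  neg <- pb
  neg$traces[, 9:16] <- max(neg$traces) - neg$traces[, 9:16]
  pcn <- pairing_correlation(neg, 2)
  expect_true(all(abs(pcn$pairs$rho + 1) < 1e-12))
  # zero-variance member: excluded with count
  flat <- pb
  flat$traces[, 9] <- 5
  pcf <- pairing_correlation(flat, 2)
  expect_equal(pcf$n_excluded, 1)
  expect_equal(sum(is.na(pcf$pairs$rho)), 1)
})

test_that("best pairing recovers every injected shift exhaustively", {
  s <- make_schedule()
  for (shift in 0:7) {
    pb <- make_pb_dataset(s, pairing_shift = shift, noise_sd = 0, seed = 1)
    bp <- best_pairing(pb)
    expect_equal(bp$shift, shift)
    expect_false(bp$tie)
    # antiphase scheme (shift + 4) is the profile minimum
    prof <- bp$profile
    expect_equal(prof$shift[which.min(prof$mean_rho)], (shift + 4) %% 8)
  }
})

test_that("best pairing survives moderate noise", {
  s <- make_schedule()
  pb <- make_pb_dataset(s, pairing_shift = 5, noise_sd = 20, seed = 11)
  expect_equal(best_pairing(pb)$shift, 5)
})

test_that("auto-correlation peak shift identifies phase-locked responses", {
  s <- make_schedule()          # AoP period 27 s
  tt <- seq(0, s$duration_s, by = 0.1)
  # exact stimulus periodicity: locked, shift ~ 0
  y <- 5 + sin(2 * pi * tt / 27)
  res <- autocorr_peak_shift(y, tt, s)
  expect_true(res$phase_locked)
  expect_lt(res$peak_shift_s, 0.3)
  # off-period sinusoid: shift ~ 2.7 s, not locked
  y2 <- 5 + sin(2 * pi * tt / 29.7)
  res2 <- autocorr_peak_shift(y2, tt, s)
  expect_false(res2$phase_locked)
  expect_equal(res2$peak_shift_s, 2.7, tolerance = 0.5)
  # generator traces are phase-locked
  tr <- simulate_response(s, phi_deg = 40, A = 1, B = 10, tau_s = 1)
  res3 <- autocorr_peak_shift(tr$f, tr$time_s, s)
  expect_true(res3$phase_locked)
})

test_that("phase-locked fraction grows as noise shrinks, and stays low for
           unmodulated traces", {
  s <- make_schedule()
  locked_frac <- function(noise_sd, A, n = 10) {
    mean(vapply(seq_len(n), function(i) {
      tr <- simulate_response(s, phi_deg = 0, A = A, B = 50,
                              noise_sd = noise_sd, seed = i, tau_s = 1)
      isTRUE(autocorr_peak_shift(tr$f, tr$time_s, s)$phase_locked)
    }, logical(1)))
  }
  expect_equal(locked_frac(0, A = 1), 1)
  hi_noise <- locked_frac(100, A = 0)
  lo_noise <- locked_frac(5, A = 1)
  expect_gte(lo_noise, hi_noise)
  expect_lt(hi_noise, 1)
})

test_that("cycle tuning is stationary for stationary pairs and tracks jumps", {
  s <- make_schedule()
  pb <- make_pb_dataset(s, pairing_shift = 0, noise_sd = 0, tau_s = 0)
  pooled <- pb_pool_pairs(pb, 0)
  ct <- cycle_tuning(pooled, pb$time_s, s)
  expect_equal(max(ct$cycle), 4)   # 2 revolutions = 4 half-rev sweeps
  for (j in 1:8) {
    aops <- ct$aop_deg[ct$pair == j]
    expect_lt(max(axial_dist(aops, aops[1])), 2)
    psis <- ct$psi[ct$pair == j]
    expect_lt(max(abs(psis - psis[1])), 0.05)
  }
  # unmodulated pair: near-zero PSI in every cycle
  flat <- pooled; flat[, 3] <- 7
  ctf <- cycle_tuning(flat, pb$time_s, s)
  expect_true(all(is.na(ctf$psi[ctf$pair == 3]) |
                    abs(ctf$psi[ctf$pair == 3]) < 1e-9))
})

test_that("a 90-degree phase jump between cycles appears in per-cycle AoPs", {
  s <- make_schedule()
  tt <- seq(0, s$duration_s, by = 0.1)
  period <- aop_period_s(s)
  t0 <- s$positions$t_on[1]
  # phase jumps 90 deg after the first sweep
  phi_t <- ifelse(tt < t0 + period, 0, 90)
  lev <- vapply(seq_along(tt), function(i) {
    k <- position_at_test(s, tt[i])
    if (is.na(k)) 1 else 1 + cos(2 * (s$positions$aop_deg[k] - phi_t[i]) * pi / 180)
  }, numeric(1))
  ct <- cycle_tuning(cbind(lev), tt, s)
  expect_lt(axial_dist(ct$aop_deg[ct$cycle == 1], 0), 5)
  expect_lt(axial_dist(ct$aop_deg[ct$cycle == 2], 90), 5)
  expect_gt(axial_dist(ct$aop_deg[ct$cycle == 1], ct$aop_deg[ct$cycle == 2]),
            85)
})

test_that("G0 analysis reproduces block-structured tuning shifts", {
  s <- make_schedule()
  # two blocks tuned 90 deg apart: pairs 1-4 at 0 deg, pairs 5-8 at 90
  phases <- c(0, 0, 0, 0, 90, 90, 90, 90)
  pb <- make_pb_dataset(s, pairing_shift = 0, phases = phases,
                        noise_sd = 0, tau_s = 0)
  pooled <- pb_pool_pairs(pb, 0)
  ct <- cycle_tuning(pooled, pb$time_s, s)
  g0 <- g0_shift_analysis(ct, threshold = 0.3, seed = 1)
  expect_true(g0$g0[1] %in% 1:8)
  own_block <- if (g0$g0[1] <= 4) 1:4 else 5:8
  expect_true(all(g0$rel_aop_deg[g0$pair %in% own_block] < 5))
  expect_true(all(g0$rel_aop_deg[!g0$pair %in% own_block] > 85))
  # homogeneous tuning: zero shift at every distance
  pb_same <- make_pb_dataset(s, pairing_shift = 0, phases = rep(30, 8),
                             noise_sd = 0, tau_s = 0)
  ct_same <- cycle_tuning(pb_pool_pairs(pb_same, 0), pb_same$time_s, s)
  g0s <- g0_shift_analysis(ct_same, threshold = 0.3, seed = 1)
  expect_true(all(g0s$rel_aop_deg < 2))
  # no qualifying cycle: recording excluded
  expect_error(g0_shift_analysis(ct_same, threshold = 2), "excluded")
  # identical seeds draw identical cycles
  a <- g0_shift_analysis(ct, threshold = 0.3, seed = 7)
  b <- g0_shift_analysis(ct, threshold = 0.3, seed = 7)
  expect_identical(a, b)
})
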