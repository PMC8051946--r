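test_that("axial mean matches the brute-force trig-sum oracle", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    ang <- runif(n, -90, 90)
    w <- runif(n, 0, 5)
    got <- axial_mean(ang, w)
    want <- oracle_axial(ang, w)
    expect_equal(got$R, want$R, tolerance = 1e-12)
    expect_lt(axial_dist(got$mean_deg, want$mean_deg), 1e-9)
  }
})

test_that("axial mean handles degenerate and grouped samples", {
  # uniform axial distribution: zero resultant, undefined angle
  u <- axial_mean(seq(0, 150, by = 30))
  expect_equal(u$R, 0, tolerance = 1e-12)
  expect_false(u$defined)
  expect_true(is.na(u$mean_deg))
  # single angle: R capped at 1 after grouping correction
  s <- axial_mean(37, weights = 2.5, grouping_deg = 30)
  expect_equal(s$R, 1)
  expect_equal(s$mean_deg, 37)
  # grouping correction closed form
  expect_equal(grouping_correction(30), (pi / 6) / sin(pi / 6),
               tolerance = 1e-12)
  expect_equal(round(grouping_correction(30), 4), 1.0472)
  expect_error(axial_mean(c(0, 10), weights = c(0, 0)), "positive")
})

test_that("Rayleigh test matches its series formula and rejects small n", {
  # plug-in check against an independently coded series evaluation
  ang <- c(0, 0, 45, 45, 90, 90, 30, 60)  # n = 8
  rt <- rayleigh_test(ang)
  n <- 8; Z <- n * rt$R^2
  p_oracle <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  expect_equal(rt$p, p_oracle, tolerance = 1e-12)
  # maximal concentration
  conc <- rayleigh_test(rep(17, 100))
  expect_equal(conc$R, 1, tolerance = 1e-12)
  expect_lt(conc$p, 1e-10)
  expect_error(rayleigh_test(c(1, 2, 3)), "at least 4")
})

test_that("Rayleigh p-values are roughly uniform under the null", {
  set.seed(21)
  ps <- replicate(200, rayleigh_test(runif(50, -90, 90))$p)
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("circular-circular correlation matches its oracle and symmetries", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    a <- runif(n, -90, 90); b <- runif(n, -90, 90)
    expect_equal(circ_circ_corr(a, b), oracle_circ_circ(a, b),
                 tolerance = 1e-12)
  }
  a <- runif(20, -90, 90)
  expect_equal(circ_circ_corr(a, a), 1, tolerance = 1e-9)
  # rotation invariance (axial offset)
  expect_equal(circ_circ_corr(a, wrap_axial(a + 40)), 1, tolerance = 1e-9)
  expect_warning(r <- circ_circ_corr(a, rep(10, 20)), "zero circular variance")
  expect_true(is.na(r))
})

test_that("Fisher-z mean has its closed-form values and symmetry", {
  expect_equal(fisher_mean(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(fisher_mean(c(0, 0.9)), tanh(atanh(0.9) / 2),
               tolerance = 1e-12)
  set.seed(41)
  r <- runif(10, -0.9, 0.9)
  expect_equal(fisher_mean(r), fisher_mean(sample(r)), tolerance = 1e-12)
  expect_warning(v <- fisher_mean(c(1, 0)), "clipped")
  expect_true(is.finite(v))
})

test_that("circular-linear fit recovers a noiseless axial gradient", {
  set.seed(51)
  x <- runif(50)
  th <- wrap_axial(-90 + 180 * x)    # one axial cycle over [0, 1]
  fit <- circ_lin_fit(x, th)
  expect_equal(abs(fit$rho), 1, tolerance = 1e-6)
  expect_equal(fit$slope_cycles, 1, tolerance = 1e-3)
  # mirrored gradient: same magnitude, opposite sign
  fit_m <- circ_lin_fit(x, wrap_axial(90 - 180 * x))
  expect_equal(fit_m$rho, -fit$rho, tolerance = 1e-6)
  expect_equal(fit_m$slope_cycles, -fit$slope_cycles, tolerance = 1e-3)
  expect_error(circ_lin_fit(rep(0.5, 10), runif(10, -90, 90)), "degenerate")
})

test_that("refined slope never beats the grid by less than the grid best", {
  set.seed(61)
  for (i in 1:10) {
    x <- runif(30)
    th <- wrap_axial(-90 + 180 * x + rnorm(30, 0, 20))
    fit <- circ_lin_fit(x, th)
    psi <- 2 * th * pi / 180
    grid <- seq(-4, 4, length.out = 1601)
    best_grid <- max(vapply(grid, function(a) {
      ph <- psi - 2 * pi * a * x
      sqrt(sum(cos(ph))^2 + sum(sin(ph))^2) / length(ph)
    }, numeric(1)))
    expect_gte(fit$resultant, best_grid - 1e-12)
  }
})

test_that("permutation test is seeded, bounded and near its floor on signal", {
  set.seed(71)
  x <- runif(50)
  th <- wrap_axial(-90 + 180 * x)
  p1 <- circ_lin_perm_test(x, th, n_perm = 200, seed = 5)
  p2 <- circ_lin_perm_test(x, th, n_perm = 200, seed = 5)
  expect_identical(p1, p2)
  expect_equal(p1$p_perm, 1 / 201)
  expect_lte(p1$p_perm, 1)
  # shuffled input: p should not concentrate near the floor
  p_null <- circ_lin_perm_test(x, sample(th), n_perm = 99, seed = 6)$p_perm
  expect_gt(p_null, 1 / 100)
})

test_that("hierarchical bootstrap CI brackets the point estimate", {
  set.seed(81)
  rhos <- list(f1 = c(0.8, 0.85, 0.75), f2 = c(0.7, 0.9), f3 = c(0.82))
  ci <- hier_bootstrap_ci(rhos, n_boot = 500, seed = 3)
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)
  # degenerate: all identical coefficients collapse the interval
  same <- hier_bootstrap_ci(list(a = c(0.5, 0.5), b = c(0.5)),
                            n_boot = 100, seed = 3)
  expect_equal(same$lower, 0.5, tolerance = 1e-12)
  expect_equal(same$upper, 0.5, tolerance = 1e-12)
  expect_error(hier_bootstrap_ci(list(a = 0.5)), "at least 2")
})

test_that("hierarchical bootstrap CI has near-nominal coverage", {
  # small two-level simulation: true mean z = atanh(0.6)
  set.seed(91)
  covered <- 0L
  n_sim <- 40
  for (s in 1:n_sim) {
    flies <- lapply(1:5, function(i) {
      z <- atanh(0.6) + rnorm(1, 0, 0.15)
      tanh(z + rnorm(3, 0, 0.1))
    })
    ci <- hier_bootstrap_ci(flies, n_boot = 400, seed = s)
    if (ci$lower <= 0.6 && 0.6 <= ci$upper) covered <- covered + 1L
  }
  expect_gte(covered / n_sim, 0.75)   # Monte-Carlo tolerance around 0.95
})

test_that("tidy and glance methods return one-row summaries", {
  set.seed(101)
  x <- runif(20)
  fit <- circ_lin_fit(x, wrap_axial(-90 + 180 * x))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("slope_cycles", "phase_deg", "rho"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 20)
})
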