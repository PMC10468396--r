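test_that("one budget step reproduces the per-capita arithmetic", {
  s <- budget_step(1000, replete_rates())
  expect_equal(s$proliferated, 1042)
  expect_equal(s$expelled, 0.2)
  expect_equal(s$digested, 35)
  expect_equal(s$next_count, 1006.8)
  expect_false(s$extinct)

  # stationarity: digestion balancing net proliferation leaves the stock flat
  p <- rate_params(mi = 0.03, expulsion = 0.001, digestion = 0.029)
  expect_equal(budget_step(5e5, p)$next_count, 5e5)

  # empty stock has no fluxes
  z <- budget_step(0, replete_rates())
  expect_equal(unlist(z[c("next_count", "proliferated", "expelled",
                          "digested")]),
               c(next_count = 0, proliferated = 0, expelled = 0, digested = 0))
})

test_that("forward run matches the closed-form geometric solution", {
  tr <- run_forward(1e6, replete_rates(), 203)
  expect_equal(nrow(tr), 204)
  expect_equal(tr$modeled_count[204], 1e6 * (1 + 0.042 - 0.0002 - 0.035)^203,
               tolerance = 1e-10)

  # proliferation alone overshoots observed growth by orders of magnitude
  fold <- run_forward(1, rate_params(0.042), 203)$modeled_count[204]
  expect_equal(fold, 1.042^203, tolerance = 1e-10)
  expect_gt(fold / 3, 1000)  # vs the ~3-fold observed expansion

  # nutrient-limited rates lose ~74 % of the stock within 50 days
  lim <- run_forward(1e6, limited_rates(), 50)
  expect_equal(lim$modeled_count[51] / 1e6, 0.9732^50, tolerance = 1e-10)
  expect_lt(lim$modeled_count[51] / 1e6, 0.5)
})

test_that("forward run equals the closed form across random parameter draws", {
  set.seed(101)
  for (i in 1:1000) {
    mi <- runif(1, 0, 0.1)
    ex <- runif(1, 0, 0.01)
    dg <- runif(1, 0, 0.08)
    nd <- sample(1:250, 1)
    s0 <- 10^runif(1, 3, 8)
    final <- run_forward(s0, rate_params(mi, ex, dg), nd)$modeled_count[nd + 1]
    closed <- s0 * (1 + mi - ex - dg)^nd
    expect_equal(final, closed, tolerance = 1e-8)
  }
})

test_that("budget conservation holds exactly at every step", {
  tr <- run_forward(2.3e6, replete_rates(), 120)
  for (i in 2:nrow(tr)) {
    expect_identical(tr$modeled_count[i],
                     tr$proliferated[i] - tr$expelled[i] - tr$digested[i])
  }
  expect_true(all(tr$modeled_count >= 0))
  expect_true(all(tr$digested >= 0))
  expect_equal(tr$cum_digested, cumsum(tr$digested))
})

test_that("increasing the digestion rate strictly decreases the final count", {
  finals <- vapply(seq(0, 0.06, by = 0.01), function(d) {
    run_forward(1e6, rate_params(0.042, 0.0002, d), 100)$modeled_count[101]
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
})

test_that("digestion-rate inference recovers the generating rate", {
  days <- seq(0, 203, by = 7)
  # noiseless trajectory generated with D = 0.035
  truth <- 1e6 * (1 + 0.042 - 0.0002 - 0.035)^days
  fit <- fit_digestion_rate(days, truth, mi = 0.042, expulsion = 0.0002)
  expect_equal(fit$d_hat, 0.035, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)

  # no digestion
  truth0 <- 1e6 * (1 + 0.042 - 0.0002)^days
  fit0 <- fit_digestion_rate(days, truth0, mi = 0.042, expulsion = 0.0002)
  expect_equal(fit0$d_hat, 0, tolerance = 1e-6)

  # threefold expansion over 203 days: the rate solving the printed budget
  fit3 <- fit_digestion_rate(c(0, 203), c(1e6, 3e6), mi = 0.042,
                             expulsion = 0.0002)
  expect_equal(fit3$d_hat, 1 + 0.042 - 0.0002 - 3^(1 / 203), tolerance = 1e-8)
  expect_equal(fit3$d_hat, 0.0364, tolerance = 1e-3)
})

test_that("digestion-rate inference is unbiased under lognormal noise", {
  days <- round(seq(0, 203, length.out = 9))
  d_true <- 0.035
  truth <- 5e6 * (1 + 0.042 - 0.0002 - d_true)^days
  sdlog <- sqrt(log(1 + 0.05^2))
  d_hat <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    obs <- truth * rlnorm(length(days), -sdlog^2 / 2, sdlog)
    fit_digestion_rate(days, obs, mi = 0.042, expulsion = 0.0002)$d_hat
  }, numeric(1))
  expect_lt(abs(mean(d_hat) - d_true), 2 * sd(d_hat))
  # bias itself is small relative to the sampling spread of the mean
  expect_lt(abs(mean(d_hat) - d_true), 3 * sd(d_hat) / sqrt(length(d_hat)))
})

test_that("missing-symbiont series measures the digestion-attributable gap", {
  # observed equals the proliferation-minus-expulsion expectation: no gap
  days <- 0:20
  expected <- 1000 * (1 + 0.042 - 0.0002)^days
  ms <- missing_symbionts(days, expected, mi = 0.042, expulsion = 0.0002)
  expect_equal(ms$missing, rep(0, length(days)), tolerance = 1e-9)

  # one step from 1000 cells with observed next count 1005
  ms1 <- missing_symbionts(c(0, 1), c(1000, 1005), mi = 0.042,
                           expulsion = 0.0002)
  expect_equal(ms1$missing, c(0, 36.8))

  # replete colony: cumulative missing cells track area increase linearly
  cfg <- noiseless_scenario()
  tc <- generate_colony_timecourse(cfg)
  ms2 <- missing_symbionts(tc$day, tc$true_count, mi = 0.042,
                           expulsion = 0.0002)
  area_gain <- tc$visible_area_cm2 - tc$visible_area_cm2[1]
  keep <- tc$day > 0
  corr <- linear_correlation(area_gain[keep], ms2$missing[keep])
  expect_gt(corr$r2, 0.99)
  expect_gt(corr$slope, 0)
})

test_that("digested cells convert to nutrient amounts elementwise", {
  out <- digested_nutrient_content(1e9, n_per_cell = 1e-8, p_per_cell = 5e-10)
  expect_equal(out$n_umol, 10)
  expect_equal(out$p_umol, 0.5)
  zero <- digested_nutrient_content(0, 1e-8, 5e-10)
  expect_equal(c(zero$n_umol, zero$p_umol), c(0, 0))
})

test_that("rate and count preconditions are enforced", {
  expect_error(rate_params(-0.01), "fraction")
  expect_error(rate_params(0, 0.5, 0.8), "exceed -1")
  expect_error(budget_step(-5, replete_rates()), "non-negative")
  expect_error(fit_digestion_rate(c(0, 10), c(0, 0), 0.042, 2e-4))
  expect_error(fit_digestion_rate(c(0, 10), c(100, -1), 0.042, 2e-4),
               "positive")
})
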