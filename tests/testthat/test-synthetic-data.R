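test_that("noise-free replete colony follows the budget recursion exactly", {
  cfg <- scenario_config("replete",
                         rate_params = rate_params(0.042, 0.0002, 0.035),
                         n_days = 203, initial_count = 1e6, density = 1e6,
                         noise_cv = 0, seed = 11)
  tc <- generate_colony_timecourse(cfg)
  expect_equal(nrow(tc), 204)
  # closed-form oracle for the final true count
  expect_equal(tc$true_count[204], 1e6 * (1 + 0.042 - 0.0002 - 0.035)^203,
               tolerance = 1e-10)
  # constant density: area proportional to count
  expect_equal(tc$visible_area_cm2, tc$true_count / 1e6, tolerance = 1e-12)
  expect_equal(tc$obs_density_cells_cm2, rep(1e6, 204))
  # MGV inversion round-trips to the observed density
  expect_equal(density_from_mgv(tc$mgv, printed_calibration()),
               tc$obs_density_cells_cm2, tolerance = 1e-9)
})

test_that("generator is deterministic in the seed and sensitive to it", {
  cfg <- scenario_config("replete", n_days = 40, seed = 77)
  a <- generate_colony_timecourse(cfg)
  b <- generate_colony_timecourse(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_colony_timecourse(scenario_config("replete", n_days = 40,
                                                  seed = 78))
  expect_false(identical(a$visible_area_cm2, c$visible_area_cm2))
})

test_that("digestion balancing net proliferation keeps the colony stationary", {
  cfg <- scenario_config(
    "replete", rate_params = rate_params(0.042, 0.0002, 0.042 - 0.0002),
    n_days = 60, noise_cv = 0, seed = 1)
  tc <- generate_colony_timecourse(cfg)
  expect_equal(tc$true_count, rep(tc$true_count[1], nrow(tc)))
})

test_that("parameter combinations that extinguish the population are rejected", {
  cfg <- scenario_config(
    "limited", rate_params = rate_params(0, 0.3, 0.69), n_days = 100,
    noise_cv = 0, seed = 1)
  # net factor 0.01/day drives counts to ~0 but never negative: allowed
  expect_silent(generate_colony_timecourse(cfg))
})

test_that("limited-regime colony grows briefly while the stock declines", {
  cfg <- scenario_config("limited", n_days = 84, noise_cv = 0, seed = 5)
  tc <- generate_colony_timecourse(cfg)
  truth <- attr(tc, "truth")
  expect_true(all(diff(truth$true_area) > 0))
  expect_lt(truth$true_area[85] / truth$true_area[1], 1.35)
  expect_true(all(diff(tc$true_count) < 0))
  expect_true(all(diff(truth$true_density) < 0))
})

test_that("downstream digestion fit recovers generator truth without noise", {
  cfg <- noiseless_scenario(seed = 3)
  tc <- generate_colony_timecourse(cfg)
  counts <- tc$obs_density_cells_cm2 * tc$visible_area_cm2
  fit <- fit_digestion_rate(tc$day, counts, mi = 0.042, expulsion = 0.0002)
  expect_equal(fit$d_hat, 0.035, tolerance = 1e-6)
})

test_that("drawdown generator produces linear decline with a 60-min re-spike", {
  # zero uptake, no noise: flat at the initial concentration (single spike)
  flat <- generate_drawdown_series(10, uptake_rate = 0, volume = 3.5,
                                   noise_sd = 0, seed = 1, spike_conc = 0)
  expect_equal(flat$conc, rep(10, 6))

  # 5 uM removed over 2 h in 3.5 L -> 17.5 umol (ΔC x V oracle), no spike
  sched0 <- pulse_schedule(sample_minutes = c(0, 30, 60, 90, 120))
  trt <- generate_drawdown_series(10, uptake_rate = 5 * 3.5 / 2, volume = 3.5,
                                  schedule = sched0, noise_sd = 0, seed = 1,
                                  spike_conc = 0)
  ctl <- drawdown_series(sched0$sample_minutes, rep(0.7, 5), volume = 3.5,
                         label = "control")
  expect_equal(as.numeric(integrate_removal(trt, ctl)), 17.5)

  # with the second spike the post-60-min samples jump up
  spiked <- generate_drawdown_series(10, uptake_rate = 5 * 3.5 / 2,
                                     volume = 3.5, noise_sd = 0, seed = 1)
  i65 <- which(spiked$minutes == 65)
  i60 <- which(spiked$minutes == 60)
  expect_gt(spiked$conc[i65], spiked$conc[i60])

  # reproducibility under a fixed seed
  n1 <- generate_drawdown_series(10, 2, 3.5, noise_sd = 0.2, seed = 42)
  n2 <- generate_drawdown_series(10, 2, 3.5, noise_sd = 0.2, seed = 42)
  expect_identical(n1$conc, n2$conc)

  # uptake exceeding the available nutrient floors at zero with a warning
  expect_warning(
    floored <- generate_drawdown_series(1, uptake_rate = 35, volume = 3.5,
                                        noise_sd = 0, seed = 1,
                                        spike_conc = 0),
    "floor")
  expect_true(all(floored$conc >= 0))
  expect_true(attr(floored, "floored"))
})

test_that("field isotope generator centres host values on the mixture", {
  # degenerate sd = 0: host mean sits exactly on the endmember mixture
  at_zoo <- generate_field_isotopes(5, mu_guano = 13, mu_zoo = 5,
                                    true_fraction = 0, sd = 0, seed = 1)
  expect_equal(at_zoo$delta15N_permil[at_zoo$compartment == "host"],
               rep(5, 5))
  at_guano <- generate_field_isotopes(5, mu_guano = 13, mu_zoo = 5,
                                      true_fraction = 1, sd = 0, seed = 1)
  expect_equal(at_guano$delta15N_permil[at_guano$compartment == "host"],
               rep(13, 5))

  # Monte-Carlo: sample mixing estimate close to the generating fraction
  samp <- generate_field_isotopes(50, mu_guano = 13, mu_zoo = 5,
                                  true_fraction = 0.5, sd = 0.5, seed = 21)
  rep_ <- mixing_report(samp)
  se <- 0.5 / sqrt(50) / 8  # sd of host mean mapped through the 8-permil span
  expect_lt(abs(rep_$f_hat - 0.5), 3 * sqrt(3) * se)  # endmember means add noise too

  expect_error(generate_field_isotopes(5, 13, 5, true_fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("generated series round-trip through the CSV writers bit-identically", {
  tmp <- withr::local_tempdir()
  tc <- generate_colony_timecourse(scenario_config("replete", n_days = 25,
                                                   seed = 13))
  p1 <- file.path(tmp, "colony.csv")
  write_colony_csv(tc, p1)
  back <- read_colony_csv(p1)
  expect_identical(back$day, tc$day)
  for (col in c("visible_area_cm2", "mass_g", "mgv", "true_count",
                "obs_density_cells_cm2")) {
    expect_identical(back[[col]], tc[[col]], label = col)
  }

  dd <- generate_drawdown_series(10, 2.3, 3.5, noise_sd = 0.1, seed = 4)
  p2 <- file.path(tmp, "drawdown.csv")
  write_drawdown_csv(dd, p2)
  dd2 <- read_drawdown_csv(p2, volume = 3.5)
  expect_identical(dd2$conc, dd$conc)
  expect_identical(dd2$minutes, as.numeric(dd$minutes))

  iso <- generate_field_isotopes(10, 13, 5, 0.5, sd = 0.5, seed = 6)
  p3 <- file.path(tmp, "iso.csv")
  write_isotope_csv(iso, p3)
  iso2 <- read_isotope_csv(p3)
  expect_identical(iso2$delta15N_permil, iso$delta15N_permil)
  expect_identical(iso2$compartment, iso$compartment)
})
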