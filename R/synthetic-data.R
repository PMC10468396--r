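#' Pulse-feeding schedule for nutrient incubations
#'
#' The dosing design of the labelling experiment: nutrient pulses on five
#' days per week, each a 2-h closed incubation sampled at fixed minutes, with
#' a second spike delivered at 60 min.
#'
#' @param pulses_per_week Pulse days per 7-day week (0-7).
#' @param pulse_hours Duration of each pulse incubation (h).
#' @param sample_minutes Sampling times within the incubation (min).
#' @return An object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(pulses_per_week = 5, pulse_hours = 2,
                           sample_minutes = c(5, 30, 60, 65, 90, 120)) {
  stopifnot(pulses_per_week >= 0, pulses_per_week <= 7, pulse_hours > 0,
            length(sample_minutes) >= 1, all(diff(sample_minutes) > 0))
  structure(list(pulses_per_week = pulses_per_week, pulse_hours = pulse_hours,
                 sample_minutes = sample_minutes),
            class = "pulse_schedule")
}

#' Scenario configuration for synthetic colony time courses
#'
#' Ground-truth parameters for one simulated colony. In the `replete` regime
#' the symbiont density stays constant, so colony area tracks the symbiont
#' count (exponential growth); in the `limited` regime the colony keeps
#' growing for a few weeks while the symbiont stock declines, so density
#' falls and the colony pales.
#'
#' @param regime `"replete"` or `"limited"`.
#' @param rate_params A [rate_params] object (the generator-side truth).
#'   Defaults to the regime's standard rates: replete MI 4.2 %/day, limited
#'   MI 0.84 %/day, expulsion 0.02 %/day, digestion 3.5 %/day.
#' @param n_days Experiment length in days (>= 1); default 203.
#' @param initial_count Initial symbiont count (cells, > 0).
#' @param density Areal symbiont density (cells/cm^2, > 0); constant truth in
#'   the replete regime and the day-0 density in the limited regime.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   observation noise (>= 0).
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @param calib_a,calib_b MGV calibration constants (`density = a*exp(b*mgv)`,
#'   `b < 0`); defaults 2e6 and -0.011.
#' @param mass_per_cm2 Colony mass per unit area (g/cm^2), used to derive the
#'   mass series from the area series.
#' @param pulse_schedule A [pulse_schedule].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(regime = c("replete", "limited"),
                            rate_params = NULL,
                            n_days = 203,
                            initial_count = 5e6,
                            density = 1e6,
                            noise_cv = 0.05,
                            seed = 1L,
                            calib_a = 2e6,
                            calib_b = -0.011,
                            mass_per_cm2 = 0.8,
                            pulse_schedule = coralfarm::pulse_schedule()) {
  regime <- match.arg(regime)
  if (is.null(rate_params)) {
    rate_params <- if (regime == "replete") {
      coralfarm::rate_params(mi = 0.042, expulsion = 0.0002, digestion = 0.035)
    } else {
      coralfarm::rate_params(mi = 0.0084, expulsion = 0.0002, digestion = 0.035)
    }
  }
  rate_params <- as_rate_params(rate_params)
  stopifnot(n_days >= 1, initial_count > 0, density > 0, noise_cv >= 0,
            mass_per_cm2 > 0, calib_a > 0,
            inherits(pulse_schedule, "pulse_schedule"))
  if (calib_b >= 0) {
    stop("`calib_b` must be negative (density decreases with brightness)",
         call. = FALSE)
  }
  structure(list(regime = regime, rate_params = rate_params,
                 n_days = as.integer(n_days), initial_count = initial_count,
                 initial_area = initial_count / density, density = density,
                 noise_cv = noise_cv, seed = as.integer(seed),
                 calib_a = calib_a, calib_b = calib_b,
                 mass_per_cm2 = mass_per_cm2,
                 pulse_schedule = pulse_schedule),
            class = "scenario_config")
}

# lognormal multiplicative noise with unit mean and coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic colony time course
#'
#' Simulates a daily colony time course whose true symbiont counts follow the
#' daily budget recursion with the configured rates. In the replete regime
#' area = count / density (constant density); in the limited regime the area
#' follows a saturating trajectory (growth stalls after a few weeks) while
#' the count declines, so density falls. MGV is obtained by inverting the
#' brightness calibration at the (noisy) observed density, so calibration
#' round trips are exact. Observed area, mass and density are the truth times
#' multiplicative lognormal noise with the configured CV; the same seed gives
#' the identical series.
#'
#' @param config A [scenario_config].
#' @param colony_id Label for the colony.
#' @return A tibble with columns `colony_id`, `day`, `visible_area_cm2`,
#'   `mass_g`, `mgv`, `true_count`, `obs_density_cells_cm2`, with the config
#'   stored in attribute `config` and the noise-free truth in attribute
#'   `truth` (tibble `day`, `true_area`, `true_density`).
#' @examples
#' cfg <- scenario_config("replete", noise_cv = 0, n_days = 30, seed = 7)
#' tc <- generate_colony_timecourse(cfg)
#' @export
generate_colony_timecourse <- function(config, colony_id = "synthetic-1") {
  stopifnot(inherits(config, "scenario_config"))
  traj <- run_forward(config$initial_count, config$rate_params, config$n_days)
  if (isTRUE(attr(traj, "extinct"))) {
    stop("parameter combination drives the symbiont population below zero ",
         "within n_days", call. = FALSE)
  }
  days <- traj$day
  true_count <- traj$modeled_count
  if (config$regime == "replete") {
    true_density <- rep(config$density, length(days))
    true_area <- true_count / config$density
  } else {
    # colony keeps growing for ~4 weeks then stagnates: saturating area with
    # a 28-day timescale and a 30 % total gain, while the count declines
    true_area <- config$initial_area * (1 + 0.3 * (1 - exp(-days / 28)))
    true_density <- true_count / true_area
  }
  withr::with_seed(config$seed, {
    obs_area <- true_area * lognormal_noise(length(days), config$noise_cv)
    obs_mass <- true_area * config$mass_per_cm2 *
      lognormal_noise(length(days), config$noise_cv)
    obs_density <- true_density * lognormal_noise(length(days), config$noise_cv)
  })
  curve <- list(a = config$calib_a, b = config$calib_b)
  mgv <- mgv_from_density(obs_density, curve)
  out <- tibble::tibble(
    colony_id = colony_id,
    day = days,
    visible_area_cm2 = obs_area,
    mass_g = obs_mass,
    mgv = mgv,
    true_count = true_count,
    obs_density_cells_cm2 = obs_density
  )
  attr(out, "config") <- config
  attr(out, "truth") <- tibble::tibble(day = days, true_area = true_area,
                                       true_density = true_density)
  out
}

#' Generate a synthetic pulse-incubation drawdown series
#'
#' Concentration declines linearly at `uptake_rate / volume` (µM/h) between
#' samples; a second spike of `spike_conc` µM is added immediately after the
#' 60-min sample (set `spike_conc = 0` for a single-spike incubation).
#' Additive Gaussian noise with standard deviation `noise_sd` is applied, and
#' concentrations are floored at zero with attribute `floored` set (uptake
#' cannot exceed the available nutrient).
#'
#' @param initial_conc Concentration at time zero (µM).
#' @param uptake_rate Constant uptake rate (µmol/h, >= 0).
#' @param volume Tank volume (L, > 0).
#' @param schedule A [pulse_schedule] supplying the sampling minutes.
#' @param noise_sd Additive measurement noise (µM, >= 0).
#' @param seed Integer seed.
#' @param spike_conc Concentration added by the second spike at 60 min (µM);
#'   defaults to `initial_conc` (same dose again).
#' @param label `"treatment"` or `"control"`.
#' @return A [drawdown_series]; attribute `floored` is TRUE if any sample hit
#'   the zero floor.
#' @examples
#' s <- generate_drawdown_series(10, uptake_rate = 8.75, volume = 3.5,
#'                               noise_sd = 0, seed = 1)
#' @export
generate_drawdown_series <- function(initial_conc, uptake_rate, volume,
                                     schedule = pulse_schedule(),
                                     noise_sd = 0, seed = 1L,
                                     spike_conc = initial_conc,
                                     label = c("treatment", "control")) {
  label <- match.arg(label)
  stopifnot(initial_conc >= 0, uptake_rate >= 0, volume > 0, noise_sd >= 0,
            spike_conc >= 0, inherits(schedule, "pulse_schedule"))
  minutes <- schedule$sample_minutes
  slope <- uptake_rate / volume  # µM per hour
  conc <- initial_conc - slope * minutes / 60
  if (spike_conc > 0) {
    post_spike <- minutes > 60
    conc[post_spike] <- conc[post_spike] + spike_conc
  }
  floored <- any(conc < 0)
  conc <- pmax(conc, 0)
  if (noise_sd > 0) {
    conc <- withr::with_seed(seed, conc + stats::rnorm(length(conc), 0, noise_sd))
    floored <- floored || any(conc < 0)
    conc <- pmax(conc, 0)
  }
  if (floored) {
    warning("drawdown hit the zero-concentration floor", call. = FALSE)
  }
  out <- drawdown_series(minutes, conc, volume, label)
  attr(out, "floored") <- floored
  out
}

#' Generate synthetic field delta-15N samples
#'
#' Emulates the bimodal field isotope survey: guano and zooplankton
#' endmember samples drawn around their means, and coral host (and symbiont)
#' samples drawn around the mixture
#' `mu_zoo + true_fraction * (mu_guano - mu_zoo)`. Macroalgae, fully reliant
#' on dissolved nutrients, are drawn around the guano mean.
#'
#' @param n_per_group Samples per compartment (>= 1).
#' @param mu_guano Guano endmember mean (per mil).
#' @param mu_zoo Zooplankton endmember mean (per mil).
#' @param true_fraction Ground-truth guano-derived fraction of host N, in
#'   \[0, 1\].
#' @param sd Within-compartment standard deviation (per mil, >= 0).
#' @param seed Integer seed.
#' @param group Group label stored with every sample (e.g. `"seabird"`).
#' @return A tibble with columns `group`, `compartment`, `delta15N_permil`;
#'   the ground truth is kept in attribute `truth`.
#' @examples
#' iso <- generate_field_isotopes(10, mu_guano = 13, mu_zoo = 5,
#'                                true_fraction = 0.5, sd = 0.5, seed = 3)
#' @export
generate_field_isotopes <- function(n_per_group, mu_guano, mu_zoo,
                                    true_fraction, sd = 0.5, seed = 1L,
                                    group = "seabird") {
  stopifnot(n_per_group >= 1, sd >= 0)
  if (true_fraction < 0 || true_fraction > 1) {
    stop("`true_fraction` must lie in [0, 1]", call. = FALSE)
  }
  mu_host <- mu_zoo + true_fraction * (mu_guano - mu_zoo)
  means <- c(host = mu_host, symbiont = mu_host, zooplankton = mu_zoo,
             guano = mu_guano, macroalgae = mu_guano)
  withr::with_seed(seed, {
    draws <- lapply(names(means), function(comp) {
      tibble::tibble(
        group = group,
        compartment = comp,
        delta15N_permil = stats::rnorm(n_per_group, means[[comp]], sd)
      )
    })
  })
  out <- do.call(rbind, draws)
  attr(out, "truth") <- list(true_fraction = true_fraction,
                             mu_guano = mu_guano, mu_zoo = mu_zoo, sd = sd)
  out
}
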