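# Canonical rate sets used across the suite.
replete_rates <- function() rate_params(mi = 0.042, expulsion = 0.0002,
                                        digestion = 0.035)
limited_rates <- function() rate_params(mi = 0.0084, expulsion = 0.0002,
                                        digestion = 0.035)

# Noise-free replete scenario for exact-recovery checks.
noiseless_scenario <- function(n_days = 203, seed = 1L, ...) {
  scenario_config("replete", n_days = n_days, noise_cv = 0, seed = seed, ...)
}

# Printed MGV calibration constants (density = a * exp(b * mgv)).
printed_calibration <- function() list(a = 2e6, b = -0.011)
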