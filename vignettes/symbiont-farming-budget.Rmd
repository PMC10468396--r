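---
title: "Symbiont farming budgets: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbiont farming budgets: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralfarm)
```

## The problem

Reef-building corals thrive in nutrient-poor water. Their dinoflagellate
symbionts can assimilate dissolved inorganic nitrate and phosphate — forms
the animal host cannot use directly — yet host tissue demonstrably gains N
and P even when particulate food is excluded. `coralfarm` implements the
quantitative argument that the host acquires these nutrients by "farming"
its symbionts: letting the population proliferate, then digesting a constant
daily fraction of it. The package provides four analysis layers plus a
synthetic-data generator with known ground truth, so that every inference
step can be validated end to end without external data.

## The population budget model

The symbiont stock is modeled in discrete daily steps. With stock
$S_{n-1}$ on the previous day,

$$P = S_{n-1}(1 + \mathrm{MI}), \qquad E = S_{n-1} E', \qquad
  D = S_{n-1} d, \qquad S_n = P - E - D,$$

where MI is the mitotic index used as the daily proliferation rate, $E'$ the
daily expulsion rate, and $d$ the daily digestion rate. All three are
per-capita fractions of the standing stock, so the model is geometric:
$S_n = S_0 (1 + \mathrm{MI} - E' - d)^n$. `run_forward()` iterates the
recursion (and is tested against the closed form); `budget_step()` exposes a
single day with exact conservation $S_n = P - E - D$.

Default rates are the experimentally determined values: MI = 0.042/day under
nutrient-replete conditions and 0.0084/day under nutrient limitation
(the main-text value 0.84 % is used where the methods also print 0.8 %; the
parameter is exposed, so either can be supplied), $E' = 0.0002$/day, and
$d = 0.035$/day. Two consequences structure the analysis:

* proliferation alone would multiply the stock ~4,240-fold in 203 days
  ($1.042^{203}$), while observed colonies only about triple — so cells must
  be removed at a substantial rate, and expulsion (0.02 %/day) is far too
  small to account for it;
* under nutrient limitation the same digestion rate with the reduced MI
  predicts losing ~74 % of the stock in 50 days
  ($0.9732^{50} \approx 0.26$), matching the observed bleaching trajectory.

`fit_digestion_rate()` inverts the model: given observed counts and known
MI and $E'$, it finds the constant $d$ minimizing the sum of squared errors
on log counts. Log-scale least squares is used because counts span orders of
magnitude and multiplicative (lognormal) observation noise is the natural
error model for them; on noise-free data the recovery is exact. The search
is a deterministic bounded 1-D minimization (`stats::optimize`, tolerance
1e-9) on $[0,\ \min(\mathrm{MI}+1,\ 1+\mathrm{MI}-E') - \varepsilon]$, the
interval on which the growth factor stays positive so the log objective is
defined; the boundary $d = 0$ is snapped exactly when it is optimal.

`missing_symbionts()` accumulates, interval by interval, the gap between the
count expected from the *observed* stock under proliferation-minus-expulsion
and the next observed count. Anchoring each interval at the observed stock
is the same accounting as the daily identity $D = P - E - S_n$ applied to
data; it keeps the cumulative gap commensurate with the standing population
(the alternative — compounding the proliferation-only expectation from day
0 — grows ~4,000-fold and measures mostly the expectation, not the data).
Under constant per-capita rates the cumulative gap is affine in the count
trajectory, which is why it correlates essentially perfectly ($r^2 > 0.99$)
with colony area gain in the replete regime.

## Growth metrics and calibrations

Surface areas come from two destructive endpoint methods — wax dipping
(`wax_area()`, 34.32 cm²/g of second-coat wax) and foil wrapping
(`foil_area()`, with the areal density estimated through the origin by
`foil_areal_density()`) — and are interpolated backwards in time by scaling
the photographic visible-area series so its final point equals the measured
total (`scale_visible_area()`; ratios between time points are preserved).

Symbiont density is inferred from image brightness: the mean grey value
(MGV) of a standardized colony photograph decreases as areal pigment density
increases, following `density = a·exp(b·MGV)` with `b < 0`.
`fit_mgv_calibration()` fits this in log space by linear regression —
deterministic, no initialization, exact on noise-free data — and reports
$r^2$ on the log scale, the scale of the fit. The reference calibration
(a = 2e6 cells/cm², b = −0.011, pooled over four species over 70 days) is
used as the generator default; pooling is unweighted since per-species
weights are not specified. MGV values outside \[0, 255\] warn rather than
error: the calibration does not bound the measurement.

Growth and decline curves (`fit_growth_curve()`) use exponential
(`y0·e^{kt}`), saturation (`y0 + A(1 − e^{-kt})`), linear and constant
families. Nonlinear families are fitted by Levenberg–Marquardt with
starting values from a log-linear fit (exponential) or the data range
(saturation); non-convergence is an error carrying the optimizer message,
never silent. $r^2 = 1 - SS_{res}/SS_{tot}$ on the original scale; the
constant family reports $r^2 = 0$ by convention since a mean-only model
explains no variance. `linear_correlation()` is plain OLS with a two-sided
t-test on the slope; an exactly collinear input yields $p = 0$ (the slope
is then known with certainty).

## Nutrient mass balance

A pulse incubation is a closed tank: nutrient removed from the water equals
nutrient taken up. `integrate_removal()` sums concentration declines times
volume over consecutive sampling intervals (piecewise-linear in
concentration, exact for linear drawdown), subtracting the control series as
background (interpolated onto the treatment grid when the grids differ).
Two numerical choices matter:

* an interval across which the treatment concentration *rises* is a
  re-spike boundary (a second nutrient dose is delivered at 60 min) and is
  excluded — a spike must not be counted as negative uptake;
* an interval where the treatment declines but the control declines faster
  yields negative net removal, which is retained with a warning rather than
  clamped, so that averaging across measurement days stays unbiased.

`area_normalized_rate()` divides by colony area and incubation duration;
`accumulate_experiment()` multiplies the rate back up over every pulse day
of the experiment (days `d` with `d mod 7 < 5` under the default
five-days-per-week schedule, 2 h per pulse), with colony area linearly
interpolated on each pulse day — the area-growth correction. Units are fixed
internally to µmol, µM, L, cm² and h.

`conversion_efficiency()` (tissue gain over dissolved uptake, as a
percentage) and `budget_closure()` (digested-symbiont N or P over host
tissue gain) close the ledger. Published per-colony totals are ambiguous
between per-colony and per-cm² normalization, so the ledger keeps a
reference area and both forms can be reported.

## Isotope tools

δ¹⁵N is computed as $((R_{sample}/R_{standard}) - 1)\times 1000$ ‰; the
standard ratio defaults to atmospheric N₂ (0.0036765), which only matters
for the optional ratio interface since all analyses work in ‰.
`enrichment_fold()` is the ratio of treated to control mean δ¹⁵N and is
defined only for positive control means; for controls at or below 0 ‰ the
ratio-scale alternative via `ratio_from_delta15n()` applies.

The two-endmember mixing model (`mixing_fraction()`) attributes host N
between guano and zooplankton sources:
$f = (\delta - \Delta - \delta_{zoo})/(\delta_{guano} - \delta_{zoo})$.
The trophic discrimination offset $\Delta$ defaults to 0 — no explicit
offset is applied in the source analysis — but is exposed because mixing
models frequently include one. Values outside \[0, 1\] are flagged, not
clamped (the sample lies outside the mixing interval). Group statistics use
arithmetic means of δ values, standard at natural abundance;
`mixing_report()` pools all samples of each endmember compartment
(island-paired endmember means are an unexplored alternative).

## The synthetic-data generator

`generate_colony_timecourse()` produces daily series whose *true* counts
follow the budget recursion exactly. In the replete regime density is
constant, so area = count/density and the colony grows exponentially; in
the limited regime the colony area saturates (28-day timescale, 30 % total
gain — growth stalls after about four weeks) while the count declines, so
density falls and the colony pales. Observed area, mass and density are the
truth times multiplicative lognormal noise (unit mean), preserving
positivity; MGV is the calibration inverse of the observed density, so
calibration round trips are exact by construction. Observation noise
magnitudes are not reported for the original experiments; the defaults
(CV 5 % for image-derived quantities, 0.01 µM for segmented-flow nutrient
analysis, 0.5 ‰ for δ¹⁵N) are chosen once as typical instrument-scale
values. `generate_drawdown_series()` declines linearly at `uptake_rate /
volume` with the second spike after 60 min and floors at zero with a
warning; `generate_field_isotopes()` draws endmember and host samples with
the host centred on the mixture with a known true fraction.

What the generator does *not* emulate: day-to-day environmental fluctuation
(rates are exactly constant), species differences (one rate set per
colony), photographic artefacts behind MGV, and tank-level covariance
between colonies. Passing tests therefore demonstrate the correctness of
the inference machinery under the model's own assumptions, not robustness
to every failure mode of real colony data.

## The pipeline and problem sizes

`run_pipeline()` chains simulate → calibrate → budget-fit → nutrient-budget
→ mixing on a single configuration and returns a report (fitted digestion
rate, conversion efficiencies, closure ratios, mixing fraction) with the
seed, a configuration hash and the package version; identical configurations
give identical reports. Pipeline defaults reproduce the scale of the
laboratory study: a colony growing ~4-fold in 203 days at 1e6 cells/cm²,
~115 µmol N and ~6 µmol P dissolved uptake per colony, per-cell contents of
3.2e-7 µmol N and 1e-8 µmol P (≈4.5 pg N, 0.3 pg P per cell), and host
assimilation fractions 1/3 (N) and 1/1.9 (P) so that digested amounts
exceed host gains by the observed ~3.0× and ~1.9×. The uptake measurement
averages three simulated incubation days, as in the uptake protocol.

Test-suite problem sizes are chosen for thorough coverage at interactive
speed: 1000 random parameter draws for the closed-form equivalence, 200
noisy replicates (9 time points, CV 5 %) for digestion-rate recovery, 200
replicates of 20 samples per compartment for mixing-fraction bias, 300
null replicates for p-value calibration. The full suite runs in well under
a minute.

## Known limitations

* The digestion rate is assumed constant; a time-varying or
  density-dependent rate cannot be distinguished by the geometric model and
  is out of scope, as is any stochastic birth–death formulation.
* Negative populations are clamped to zero with an explicit flag rather
  than raising, so depletion scenarios run to completion; with valid rates
  (net factor > 0) the clamp never triggers.
* The mixing model is strictly two-source and linear; multi-source or
  concentration-dependent Bayesian mixing is not implemented.
* Mass and visible area enter the generator as proportional to true area;
  calcification dynamics are not modeled separately.
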