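# coralfarm

Quantitative analysis of how reef-building corals acquire nitrogen and
phosphorus by "farming" their algal symbionts: letting the population
proliferate on dissolved inorganic nutrients that the animal host cannot
assimilate itself, then digesting a constant daily fraction of the symbiont
stock. The package is aimed at coral physiologists and biogeochemists who
want to run the budget arithmetic on their own colony time courses, and at
anyone auditing the inference chain behind it.

## The model

The symbiont stock evolves in discrete daily steps. With stock *S*ₙ₋₁ on the
previous day,

```
P = S(n-1) · (1 + MI)      proliferation (MI = mitotic index, /day)
E = S(n-1) · E'            expulsion (E' ≈ 0.0002 /day)
D = S(n-1) · d             digestion (d = daily digestion rate)
S(n) = P − E − D           conservation, exact
```

so the population is geometric: `S(n) = S(0)·(1 + MI − E' − d)^n`. Because
the measured mitotic index (4.2 %/day, nutrient-replete) would multiply the
stock ~4,200-fold in 203 days while colonies only roughly triple, and
expulsion is negligible, a substantial daily removal is required; the
package infers that digestion rate `d` from observed counts by bounded
1-D least squares on log counts (`fit_digestion_rate()`).

Around the core model sit the supporting analyses:

* **growth metrics** — wax-dipping and foil surface areas, visible-area
  anchoring, the MGV (image brightness) → symbiont density calibration
  `density = a·e^(b·MGV)`, growth-curve fits, linear correlations;
* **nutrient budget** — integration of pulse-incubation drawdown curves
  (with the 60-min re-spike excluded), control subtraction, area
  normalization, accumulation over the experiment with the area-growth
  correction, conversion efficiencies and digested-vs-host-gain closure
  ratios;
* **isotope tools** — δ¹⁵N arithmetic, treatment/control enrichment folds,
  and the two-endmember guano/zooplankton mixing model for the fraction of
  host N traceable to seabird-derived nutrients;
* **synthetic data** — generators for colony time courses, drawdown series
  and field isotope surveys with known ground truth, so every stage is
  testable end to end.

## Worked example

A population that triples over the 203-day experiment (the observed area
expansion at constant symbiont density), with the measured mitotic index and
expulsion rate:

```r
library(coralfarm)

fit <- fit_digestion_rate(c(0, 203), c(1e6, 3e6), mi = 0.042, expulsion = 0.0002)
round(100 * fit$d_hat, 2)
#> [1] 3.64
```

3.64 % of the standing symbiont stock digested per day — inside the
experimentally determined 3.5 ± 0.7 %/day. Running the budget forward with
the central rates shows where the cells go:

```r
tr <- run_forward(1e6, rate_params(0.042, 0.0002, 0.035), 203)
tail(tr, 2)
#> # A tibble: 2 × 6
#>     day modeled_count proliferated expelled digested cum_digested
#>   <int>         <dbl>        <dbl>    <dbl>    <dbl>        <dbl>
#> 1   202      3931224.     4068668.     781.  136664.    15087182.
#> 2   203      3957956.     4096335.     786.  137593.    15224775.
```

The colony ends with ~4.0 million symbionts but has digested ~15.2 million
along the way — the nutrient stream feeding host growth. The full synthetic
pipeline (simulate → calibrate → fit → mass balance → isotope mixing):

```r
print(run_pipeline(pipeline_config(seed = 42)))
#> Symbiont-farming pipeline report
#>   fitted digestion rate: 0.0361 /day
#>   conversion efficiency N: symbiont 4.11 %, host 7.05 %
#>   conversion efficiency P: symbiont 1.78 %, host 4.83 %
#>   budget closure (digested/host gain): N 3.00, P 1.90
#>   guano-derived fraction of host N: 0.503
#>   seed 42, config ac101b98b9feccb1b437b66749fbd97e, coralfarm 0.1.0
```

The digestion rate recovered from the noisy simulated colony (0.0361/day)
is close to the generator truth (0.035); the closure ratios say the digested
symbiont fraction carried ~3.0× the N and ~1.9× the P that the host tissue
gained — digestion alone can supply host growth; and the mixing model
recovers the configured 50 % guano contribution to host N.

The `analysis/` directory contains the same workflow as numbered scripts
(`01_simulate.R` … `05_isotope_mixing.R`), each writing its tables under
`results/`.

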