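#!/usr/bin/env Rscript
# Stage 2: calibrate observables and fit the growth/decline curves.
#
# Fits the MGV -> symbiont-density calibration on the simulated colony,
# anchors the visible-area series to a wax-dipping total area, and fits the
# standard curve families (exponential growth, exponential decline of the
# limited colony's density, constant density of the replete colony).

suppressPackageStartupMessages(library(coralfarm))

tc <- read_colony_csv("results/simulated/colony_replete.csv")
lim <- read_colony_csv("results/simulated/colony_limited.csv")

calib <- fit_mgv_calibration(c(tc$mgv, lim$mgv),
                             c(tc$obs_density_cells_cm2,
                               lim$obs_density_cells_cm2))
print(calib)

# final total area as a wax-dipping measurement of the last time point
final_total <- wax_area(tc$visible_area_cm2[nrow(tc)] / 34.32)
tc <- scale_visible_area(tc, final_total)

fits <- list(
  replete_area = fit_growth_curve(tc$day, tc$total_area, "exp_increase"),
  replete_density = fit_growth_curve(tc$day, tc$obs_density_cells_cm2,
                                     "constant"),
  limited_density = fit_growth_curve(lim$day, lim$obs_density_cells_cm2,
                                     "exp_decrease"),
  limited_area = fit_growth_curve(lim$day, lim$visible_area_cm2, "saturation")
)
for (nm in names(fits)) {
  message(sprintf("%-16s family %-12s r2 = %.3f params: %s", nm,
                  fits[[nm]]$family, fits[[nm]]$r2,
                  paste(sprintf("%s=%.4g", names(fits[[nm]]$params),
                                unlist(fits[[nm]]$params)), collapse = ", ")))
}

jsonlite::write_json(
  list(calibration = calib[c("a", "b", "r2", "n")],
       fits = lapply(fits, function(f) f[c("family", "params", "r2")])),
  "results/growth_fits.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/growth_fits.json")
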