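#!/usr/bin/env Rscript
# Stage 3 — thermal seasons and growing-season covariates.
#
# Segments the simulated weather year into thermal seasons (run-length
# rule on daily mean temperature) and derives, for each measurement DOY,
# the covariates later correlated with the flavonol index: days post
# snowmelt, days before first marked snowfall, days from growing-season
# start, and the effective temperature sum (base +5 degrees C).

suppressPackageStartupMessages(library(photodose))

wtab <- read.csv("results/simulated/weather.csv")
weather <- daily_weather(wtab$date, wtab$t_mean, wtab$t_min, wtab$t_max,
                         wtab$snow_depth_cm)
seg <- segment_thermal_seasons(weather, N = 5)
print(seg)

doys <- sort(unique(read.csv("results/simulated/iflav_records.csv")$doy))
cov <- do.call(rbind, lapply(doys, function(d)
  growing_season_variables(weather, seg, d, T_base = 5)))
write.csv(cov, "results/weather_covariates.csv", row.names = FALSE)
message("covariates at measurement DOYs:")
print(cov, row.names = FALSE)
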