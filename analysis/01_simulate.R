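#!/usr/bin/env Rscript
# Stage 1 — simulate the field campaign.
#
# Generates the default five-stand scenario: a weather year with
# snowpack, spectral irradiance at sunfleck/shade/leaf positions for
# four points per stand on four measurement DOYs, and the understorey
# flavonol-index survey with its abundance table. Everything downstream
# reads only the files written here.

suppressPackageStartupMessages(library(photodose))

seed <- 1
out <- "results/simulated"
dir.create(file.path(out, "spectra"), recursive = TRUE,
           showWarnings = FALSE)

cfg <- scenario_config()
weather <- gen_weather_year(cfg$weather, seed = seed)
write.csv(weather, file.path(out, "weather.csv"), row.names = FALSE)

gen <- gen_stand_spectra(cfg, seed = seed + 1L)
for (i in seq_along(gen$spectra)) {
  s <- gen$spectra[[i]]
  write_spectrum(s, file.path(out, "spectra",
                              sprintf("%s_doy%03d_%s_%s.csv",
                                      s$meta$stand, s$meta$doy,
                                      s$meta$position, s$meta$point)))
}

doses_for_survey <- dose_table(gen$spectra)
survey <- gen_community_survey(cfg, doses_for_survey, weather,
                               seed = seed + 2L)
write.csv(survey$records, file.path(out, "iflav_records.csv"),
          row.names = FALSE)
write.csv(survey$abundances, file.path(out, "abundances.csv"),
          row.names = FALSE)
write_truth <- function(x, path)  # planted truth as plain text
  write.csv(data.frame(parameter = c("beta_uva", "gamma_cold", "t_cold",
                                     "sigma_e", "sigma_point", "rho_cs"),
                       value = c(x$beta_uva, x$gamma_cold, x$t_cold,
                                 x$sigma_e, x$sigma_point, x$rho_cs)),
            path, row.names = FALSE)
write_truth(survey$truth, file.path(out, "truth.csv"))

message(sprintf("simulated %d spectra, %d survey records (%d species), seed %d",
                length(gen$spectra), nrow(survey$records),
                length(unique(survey$records$species)), seed))
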