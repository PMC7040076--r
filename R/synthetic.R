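# Synthetic-data generator emulating the field measurement design: a
# parametric solar spectrum filtered through canopy scenarios, a weather
# year with snowpack, and a community survey of the flavonol index whose
# response structure (linear in shade UV-A dose, cold-response hinge,
# point random effect giving compound-symmetry correlation) makes every
# downstream statistic recoverable against planted truth.

#' Scenario configuration for the synthetic generator
#'
#' The default scenario mirrors the field design: five stands (three
#' birch-type deciduous of different ages, one evergreen spruce-type with
#' high flat plant area index, one oak-type deciduous with delayed
#' leaf-out), four measurement points per stand, four measurement DOYs
#' spanning spring to mid-summer, and a 35-species understorey community.
#'
#' @param stands data.frame with `stand`, `canopy` (deciduous|evergreen),
#'   `pai_winter`, `pai_summer`, `leafout_doy`, `leafout_rate`.
#' @param doys measurement days of year.
#' @param n_points measurement points per stand.
#' @param n_species species pool size.
#' @param n_plants plants measured per species per point.
#' @param beta_uva planted slope of the flavonol index on shade UV-A
#'   photon irradiance (index units per µmol m⁻² s⁻¹).
#' @param gamma_cold planted cold-response slope (index units per °C
#'   below `t_cold`).
#' @param t_cold hinge temperature (°C) for the cold response.
#' @param sigma_e residual SD of the index.
#' @param sigma_point SD of the point random effect (sets the
#'   compound-symmetry correlation sigma_point² / (sigma_point² +
#'   sigma_e²)).
#' @param sunfleck_cv,shade_cv,leaf_cv lognormal coefficients of
#'   variation of the per-point spectral measurements by position
#'   (sunflecks are far more variable than diffuse shade).
#' @param weather list of weather-year parameters: `t_annual_mean`,
#'   `t_amplitude`, `t_coldest_doy`, `ar1_phi`, `noise_sd`,
#'   `t_half_range`, `snow_init_cm`.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(
    stands = data.frame(
      stand = c("Betula_old", "Betula_mixed", "Betula_young",
                "Picea", "Quercus"),
      canopy = c("deciduous", "deciduous", "deciduous", "evergreen",
                 "deciduous"),
      pai_winter = c(0.8, 1.0, 0.7, 4.5, 0.9),
      pai_summer = c(3.5, 4.0, 3.2, 4.8, 3.8),
      leafout_doy = c(130, 132, 128, NA, 140),
      leafout_rate = c(0.12, 0.12, 0.12, NA, 0.12),
      stringsAsFactors = FALSE),
    doys = c(115, 143, 156, 202),
    n_points = 4,
    n_species = 35,
    n_plants = 4,
    beta_uva = 0.04,
    gamma_cold = 0.02,
    t_cold = 5,
    sigma_e = 0.15,
    sigma_point = 0.08,
    sunfleck_cv = 0.5,
    shade_cv = 0.10,
    leaf_cv = 0.20,
    weather = list(t_annual_mean = 4, t_amplitude = 13, t_coldest_doy = 15,
                   ar1_phi = 0.7, noise_sd = 2, t_half_range = 3,
                   snow_init_cm = 30)) {
  stopifnot(sigma_e > 0, sigma_point >= 0, n_points >= 1)
  structure(list(stands = stands, doys = doys, n_points = n_points,
                 n_species = n_species, n_plants = n_plants,
                 beta_uva = beta_uva, gamma_cold = gamma_cold,
                 t_cold = t_cold, sigma_e = sigma_e,
                 sigma_point = sigma_point, sunfleck_cv = sunfleck_cv,
                 shade_cv = shade_cv, leaf_cv = leaf_cv,
                 weather = weather),
            class = "scenario_config")
}

#' Parametric open-field solar spectrum
#'
#' A smooth photon-irradiance template on the 280-900 nm analysis range
#' (0.5 nm grid): a fixed envelope shape times a logistic UV-B cut-on
#' whose midpoint shifts to longer wavelengths at low solar elevation
#' (longer ozone path), times an elevation-dependent amplitude. The
#' default midsummer-noon parameters are calibrated so band integrals
#' match open-field magnitudes (PPFD ~1350 µmol m⁻² s⁻¹, UV-B:PPFD
#' ~0.0009); it is a band-level template, not a radiative-transfer model.
#'
#' @param elevation_deg solar elevation angle, in (0, 90].
#' @param diffuse_fraction fraction of the global irradiance that is
#'   diffuse sky radiation; carried as an attribute for [apply_canopy()].
#' @param amplitude overall amplitude at the reference elevation.
#' @return a [spectral_irradiance()] (photon units, position `"open"`)
#'   with attribute `diffuse_fraction`.
#' @export
gen_solar_spectrum <- function(elevation_deg, diffuse_fraction = 0.15,
                               amplitude = 1) {
  if (elevation_deg <= 0 || elevation_deg > 90)
    stop("solar elevation must be in (0, 90] degrees")
  grid <- seq(280, 900, by = 0.5)
  # envelope: relative photon irradiance, smooth through fixed anchors
  anchors_l <- c(280, 300, 315, 330, 350, 375, 400, 430, 460, 500, 550,
                 600, 650, 700, 750, 800, 850, 900)
  anchors_v <- c(0.30, 0.32, 0.36, 0.80, 1.15, 1.45, 1.70, 3.60, 4.30,
                 4.50, 4.60, 4.70, 4.60, 4.40, 4.20, 3.90, 3.60, 3.30)
  env <- pmax(0, stats::spline(anchors_l, anchors_v, xout = grid,
                               method = "natural")$y)
  m_ref <- 1 / sin(52 * pi / 180)          # midsummer-noon reference
  m <- 1 / sin(elevation_deg * pi / 180)   # relative airmass proxy
  cuton_mid <- 311 + 2.0 * (m - m_ref)
  cuton <- 1 / (1 + exp(-(grid - cuton_mid) / 2.0))
  amp <- amplitude * (sin(elevation_deg * pi / 180) / sin(52 * pi / 180))^1.2
  spectral_irradiance(grid, amp * env * cuton, unit = "photon",
                      position = "open") -> s
  attr(s, "diffuse_fraction") <- diffuse_fraction
  s
}

# leaf transmittance: low in UV and PAR, green bump, high beyond 700 nm
.leaf_transmittance <- function(l) {
  0.02 + 0.10 * exp(-((l - 550) / 40)^2) +
    0.43 / (1 + exp(-(l - 710) / 15))
}

#' Filter an open spectrum through a canopy scenario
#'
#' Position semantics: `sunfleck` is the direct beam plus canopy-
#' transmitted diffuse light, with only weak neutral attenuation of the
#' beam; `shade` (trunk umbra) is the diffuse component transmitted
#' through gap fraction exp(-k·PAI), with a mild UV enrichment relative
#' to PAR that grows with canopy density (diffuse sky light is UV-rich);
#' `leaf` is the shade spectrum additionally filtered by a leaf
#' transmittance spectrum (low in UV and PAR, green bump, high beyond
#' 700 nm, hence a depressed red:far-red ratio). With `pai = 0` the
#' output equals the input exactly for every position except `leaf`.
#'
#' @param spectrum an open-field [spectral_irradiance()] carrying a
#'   `diffuse_fraction` attribute (see [gen_solar_spectrum()]).
#' @param position `"sunfleck"`, `"shade"` or `"leaf"`.
#' @param pai plant area index (m² m⁻²), >= 0.
#' @param k diffuse extinction coefficient, default 0.5.
#' @param k_umbra extinction of the direct component inside an umbra,
#'   default 2.
#' @return the filtered [spectral_irradiance()] with `position` set.
#' @export
apply_canopy <- function(spectrum, position, pai, k = 0.5, k_umbra = 2) {
  stopifnot(inherits(spectrum, "spectral_irradiance"))
  if (pai < 0) stop("PAI must be >= 0")
  if (!position %in% c("sunfleck", "shade", "leaf"))
    stop("unknown position: ", position)
  df <- attr(spectrum, "diffuse_fraction") %||% 0.15
  l <- spectrum$wavelengths_nm
  uv_enrich <- 1 + 0.3 * pmax(0, pmin(1, (450 - l) / 170)) *
    (1 - exp(-pai))
  shade_factor <- (1 - df) * exp(-k_umbra * pai) +
    df * exp(-k * pai) * uv_enrich
  factor <- switch(position,
    sunfleck = (1 - df) * exp(-0.05 * pai) + df * exp(-k * pai),
    shade = shade_factor,
    leaf = shade_factor * .leaf_transmittance(l))
  out <- spectrum
  out$values <- spectrum$values * factor
  out$meta$position <- position
  attr(out, "clip_count") <- attr(spectrum, "clip_count")
  attr(out, "diffuse_fraction") <- df
  out
}

# solar noon elevation at ~61 N as a function of DOY
.noon_elevation <- function(doy) {
  decl <- 23.44 * sin(2 * pi * (doy - 81) / 365.25)
  pmax(1, 90 - 61 + decl)
}

# stand PAI trajectory: evergreen flat, deciduous logistic leaf-out
.stand_pai <- function(stand_row, doy) {
  if (stand_row$canopy == "evergreen" || is.na(stand_row$leafout_doy))
    return(stand_row$pai_winter +
             (stand_row$pai_summer - stand_row$pai_winter) * 0.9)
  stand_row$pai_winter +
    (stand_row$pai_summer - stand_row$pai_winter) /
    (1 + exp(-stand_row$leafout_rate * (doy - stand_row$leafout_doy)))
}

#' Synthetic weather year
#'
#' Daily mean temperature is an annual sinusoid plus AR(1) noise;
#' min/max are the mean -/+ a fixed half-range; snow depth follows a
#' deterministic accumulation/melt envelope driven by the realised daily
#' mean (accumulating below 0 °C, melting above).
#'
#' @param params weather parameter list (see [scenario_config()]).
#' @param year calendar year for the date column, default 2015.
#' @param seed integer seed; identical seed and parameters give an
#'   identical series.
#' @return a [daily_weather()] for the full year.
#' @export
gen_weather_year <- function(params = scenario_config()$weather,
                             year = 2015, seed = 1) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  n <- length(dates)
  doy <- seq_len(n)
  base <- params$t_annual_mean - params$t_amplitude *
    cos(2 * pi * (doy - params$t_coldest_doy) / n)
  noise <- numeric(n)
  if (params$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    innov <- stats::rnorm(n, 0, params$noise_sd *
                            sqrt(1 - params$ar1_phi^2))
    noise[1] <- stats::rnorm(1, 0, params$noise_sd)
    for (i in 2:n) noise[i] <- params$ar1_phi * noise[i - 1] + innov[i]
  }
  t_mean <- base + noise
  snow <- numeric(n)
  depth <- params$snow_init_cm
  for (i in seq_len(n)) {
    depth <- if (t_mean[i] < 0) depth + 0.4 * (-t_mean[i])
             else max(0, depth - 1.2 * t_mean[i])
    snow[i] <- depth
  }
  daily_weather(dates, t_mean, t_mean - params$t_half_range,
                t_mean + params$t_half_range, snow)
}

# save/restore global RNG state so generators are self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate the stand spectra for a scenario
#'
#' One spectrum per stand × DOY × position × point: the open solar
#' template at that DOY's noon elevation, filtered by the stand's PAI
#' trajectory, with per-point lognormal measurement variability (largest
#' for sunflecks, smallest for diffuse shade).
#'
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return list with `spectra` (list of [spectral_irradiance()]) and
#'   `open` (list of the per-DOY open spectra).
#' @export
gen_stand_spectra <- function(config, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  spectra <- list()
  open <- list()
  for (d in config$doys) {
    sun <- gen_solar_spectrum(.noon_elevation(d))
    sun$meta$doy <- d
    sun$meta$stand <- "Open"
    open[[as.character(d)]] <- sun
    for (si in seq_len(nrow(config$stands))) {
      srow <- config$stands[si, ]
      pai <- .stand_pai(srow, d)
      for (pt in seq_len(config$n_points)) {
        pai_pt <- pai * exp(stats::rnorm(1, 0, 0.05))
        for (pos in c("sunfleck", "shade", "leaf")) {
          cv <- switch(pos, sunfleck = config$sunfleck_cv,
                       shade = config$shade_cv, leaf = config$leaf_cv)
          s <- apply_canopy(sun, pos, pai_pt)
          s$values <- s$values * exp(stats::rnorm(1, -cv^2 / 2, cv))
          s$meta$stand <- srow$stand
          s$meta$doy <- d
          s$meta$point <- sprintf("P%d", pt)
          spectra[[length(spectra) + 1L]] <- s
        }
      }
    }
  }
  list(spectra = spectra, open = open)
}

#' Generate a community flavonol-index survey with planted truth
#'
#' Each plant's index follows
#' `iflav = beta0_s + beta_uva * D_UVA_shade(stand, doy) +
#'  gamma_cold * max(0, t_cold - t_min(doy)) + b_point + e`,
#' with `b_point ~ N(0, sigma_point²)` shared by all records at a
#' measurement point (giving compound-symmetry correlation within
#' points) and `e ~ N(0, sigma_e²)`; values are clipped at 0. The
#' planted parameters are returned in `truth` for recovery tests.
#'
#' @param config a [scenario_config()].
#' @param doses dose table ([dose_table()]) covering every stand × DOY at
#'   the shade position; the stand-level mean shade UV-A drives the
#'   response.
#' @param weather a [daily_weather()] supplying `t_min` per DOY.
#' @param seed integer seed.
#' @return list with `records` (flavonol-index records), `abundances`
#'   (relative-abundance table) and `truth` (planted parameters).
#' @export
gen_community_survey <- function(config, doses, weather, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shade <- doses[doses$position == "shade", ]
  dose_uva <- stats::aggregate(UVA ~ stand + doy, shade, mean)
  need <- expand.grid(stand = config$stands$stand, doy = config$doys,
                      stringsAsFactors = FALSE)
  have <- paste(dose_uva$stand, dose_uva$doy)
  if (!all(paste(need$stand, need$doy) %in% have))
    stop("dose table missing shade rows for some stand x DOY")
  species <- sprintf("sp%02d", seq_len(config$n_species))
  beta0 <- stats::rnorm(config$n_species, 1.0, 0.25)
  names(beta0) <- species
  records <- list()
  abund <- list()
  for (si in seq_len(nrow(config$stands))) {
    st <- config$stands$stand[si]
    for (pt in seq_len(config$n_points)) {
      point <- sprintf("P%d", pt)
      n_here <- min(sample(8:14, 1), config$n_species)
      present <- sample(species, n_here)
      w <- stats::rgamma(n_here, shape = 2)
      abund[[length(abund) + 1L]] <- data.frame(
        stand = st, point = point, species = present,
        rel_abundance = w / sum(w), stringsAsFactors = FALSE)
      b_point <- stats::rnorm(1, 0, config$sigma_point)
      for (d in config$doys) {
        duva <- dose_uva$UVA[dose_uva$stand == st & dose_uva$doy == d]
        tmin <- weather$t_min[min(d, nrow(weather))]
        cold <- config$gamma_cold * max(0, config$t_cold - tmin)
        measured <- sample(present, max(3, round(0.8 * n_here)))
        for (sp in measured) {
          mu <- beta0[sp] + config$beta_uva * duva + cold + b_point
          vals <- pmax(0, mu + stats::rnorm(config$n_plants, 0,
                                            config$sigma_e))
          records[[length(records) + 1L]] <- data.frame(
            plant_id = sprintf("%s_%s_%s_%d_%d", st, point, sp, d,
                               seq_len(config$n_plants)),
            species = sp, stand = st, point = point, doy = d,
            year = 2015L, leaf_side = "adaxial", leaf_age = "mature",
            iflav = vals, stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- list(beta0 = beta0, beta_uva = config$beta_uva,
                gamma_cold = config$gamma_cold, t_cold = config$t_cold,
                sigma_e = config$sigma_e, sigma_point = config$sigma_point,
                rho_cs = config$sigma_point^2 /
                  (config$sigma_point^2 + config$sigma_e^2))
  list(records = do.call(rbind, records),
       abundances = do.call(rbind, abund), truth = truth)
}
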