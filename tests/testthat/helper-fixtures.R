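# Shared in-code fixtures: spectra with known closed-form integrals and a
# small worked community survey.

flat_spectrum <- function(value = 1, lo = 280, hi = 900, by = 0.5,
                          unit = "photon", ...) {
  g <- seq(lo, hi, by = by)
  spectral_irradiance(g, rep(value, length(g)), unit = unit, ...)
}

quadratic_spectrum <- function(a = 0.5, b = 0.002, cc = 1e-5,
                               lo = 280, hi = 900, by = 0.5) {
  g <- seq(lo, hi, by = by)
  spectral_irradiance(g, a + b * g + cc * g^2, unit = "photon")
}

# smooth positive random spectrum (random Fourier modes on a baseline)
random_smooth_spectrum <- function(lo = 280, hi = 900, by = 0.5) {
  g <- seq(lo, hi, by = by)
  v <- 2 + sin(2 * pi * g / stats::runif(1, 150, 400)) +
    0.5 * cos(2 * pi * g / stats::runif(1, 50, 120)) +
    stats::runif(1, 0, 1)
  spectral_irradiance(g, v, unit = "photon")
}

# piecewise-constant synthetic weather year used in the segmentation oracle
step_weather_year <- function() {
  t <- c(rep(-5, 90), rep(5, 60), rep(15, 90), rep(5, 60), rep(-5, 65))
  daily_weather(seq(as.Date("2015-01-01"), by = "day",
                    length.out = length(t)),
                t_mean = t, t_min = t - 1, t_max = t + 1,
                snow_depth_cm = c(rep(30, 99), rep(0, 266)))
}

# grouped design with planted slope, CS correlation rho and optional
# heteroscedastic strata (sigma_i = sigma * strata_sd[stratum])
sim_cs <- function(n_groups = 20, m = 8, beta = c(1, 0.02), rho = 0.5,
                   sigma = 1, strata_sd = NULL) {
  g <- rep(seq_len(n_groups), each = m)
  x <- stats::runif(n_groups * m, 0, 50)
  X <- cbind(1, x)
  b_g <- stats::rnorm(n_groups, 0, sigma * sqrt(rho))
  e <- stats::rnorm(n_groups * m, 0, sigma * sqrt(1 - rho))
  y <- as.vector(X %*% beta) + b_g[g] + e
  stratum <- NULL
  if (!is.null(strata_sd)) {
    stratum <- rep(rep(seq_along(strata_sd), length.out = m), n_groups)
    y <- as.vector(X %*% beta) + (b_g[g] + e) * strata_sd[stratum]
  }
  list(y = y, X = X, group = g, stratum = stratum)
}

# tiny two-species survey with exact hand-computable CWM
toy_survey <- function() {
  records <- data.frame(
    plant_id = paste0("p", 1:6),
    species = rep(c("A", "B"), each = 3),
    stand = "S1", point = "P1", doy = 100, year = 2015L,
    leaf_side = "adaxial", leaf_age = "mature",
    iflav = c(1, 1, 1, 2, 2, 2), stringsAsFactors = FALSE)
  abundances <- data.frame(
    stand = "S1", point = "P1", species = c("A", "B"),
    rel_abundance = c(0.6, 0.4), stringsAsFactors = FALSE)
  list(records = records, abundances = abundances)
}
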