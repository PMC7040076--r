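# Spectral objects: I/O round trip, unit conversion, resampling and
# waveband integration.

test_that("spectrum CSV round-trips with metadata and clips negatives", {
  s <- flat_spectrum(2, stand = "S1", doy = 142, position = "shade",
                     point = "P3")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$wavelengths_nm, s$wavelengths_nm)
  expect_equal(s2$values, s$values)
  expect_equal(s2$meta$stand, "S1")
  expect_equal(s2$meta$doy, 142L)
  expect_equal(s2$meta$position, "shade")
  expect_equal(s2$unit, "photon")

  # negative ingest value clipped, clip count logged
  writeLines(c("# unit=photon", "wavelength_nm,value",
               "300,1", "301,-0.01", "302,1"), path)
  s3 <- read_spectrum(path)
  expect_equal(s3$values, c(1, 0, 1))
  expect_equal(attr(s3, "clip_count"), 1L)
})

test_that("malformed spectrum files are hard errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# unit=photon", "wavelength_nm,value",
               "300,1", "299,1", "301,1"), path)
  expect_error(read_spectrum(path), "non-monotone")
  writeLines(c("# unit=photon", "wl,value", "300,1", "301,1"), path)
  expect_error(read_spectrum(path), "missing columns")
})

test_that("energy to photon conversion matches the hc/lambda oracle", {
  g <- c(400, 500, 700)
  s <- spectral_irradiance(g, c(1, 1, 0), unit = "energy")
  p <- energy_to_photon(s)
  # independent oracle: lambda / (h c N_A), evaluated from the constants
  oracle <- function(l) (l * 1e-9) /
    (6.62607015e-34 * 2.99792458e8 * 6.02214076e23) * 1e6
  expect_equal(p$values[1], oracle(400), tolerance = 1e-6)
  expect_equal(p$values[2], oracle(500), tolerance = 1e-6)
  expect_identical(p$values[3], 0)
  expect_equal(p$unit, "photon")
  expect_error(energy_to_photon(p), "not in energy units")
  # strictly increasing in lambda for equal energy; exact factor 2 at 800/400
  s2 <- spectral_irradiance(seq(400, 800, 100), rep(1, 5), unit = "energy")
  v <- energy_to_photon(s2)$values
  expect_true(all(diff(v) > 0))
  expect_equal(v[5] / v[1], 2, tolerance = 1e-12)
})

test_that("resampling interpolates linearly and preserves integrals", {
  s <- spectral_irradiance(c(400, 402), c(1, 3), unit = "photon")
  expect_equal(resample_spectrum(s, c(400, 401, 402))$values[2], 2)
  s2 <- flat_spectrum(5)
  expect_equal(resample_spectrum(s2, s2$wavelengths_nm)$values, s2$values)
  expect_error(resample_spectrum(s2, c(100, 300)), "outside source coverage")

  # integral before vs after resampling a smooth spectrum to 0.1 nm
  q <- quadratic_spectrum()
  fine <- resample_spectrum(q, seq(280, 900, 0.1))
  par_band <- canonical_bands()$PAR
  expect_equal(integrate_band(fine, par_band), integrate_band(q, par_band),
               tolerance = 1e-3)
  # superset grid changes band integrals by < 1e-6 relative
  sup <- resample_spectrum(q, sort(union(q$wavelengths_nm,
                                         seq(280.25, 899.75, 0.5))))
  for (b in canonical_bands())
    expect_equal(integrate_band(sup, b), integrate_band(q, b),
                 tolerance = 1e-6)
})

test_that("waveband integration: flat-spectrum widths and quadratic oracle", {
  s <- flat_spectrum(1)
  b <- canonical_bands()
  expect_equal(integrate_band(s, b$UVA), 85)
  expect_equal(integrate_band(s, b$UVB), 35)
  expect_equal(integrate_band(s, b$PAR), 300)
  expect_error(integrate_band(flat_spectrum(1, lo = 400, hi = 900), b$UVB),
               "insufficient coverage")
  expect_error(integrate_band(spectral_irradiance(c(300, 400), c(1, 1),
                                                  unit = "energy"), b$UVB),
               "photon units")

  # closed-form antiderivative oracle for a quadratic spectrum over PAR
  a <- 0.5; bb <- 0.002; cc <- 1e-5
  q <- quadratic_spectrum(a, bb, cc)
  anti <- function(l) a * l + bb * l^2 / 2 + cc * l^3 / 3
  expect_equal(integrate_band(q, b$PAR), anti(700) - anti(400),
               tolerance = 1e-6)
})

test_that("integration is linear and adjacent bands partition exactly", {
  set.seed(42)
  uv <- waveband("UV", 280, 400)
  b <- canonical_bands()
  for (i in 1:100) {
    s1 <- random_smooth_spectrum()
    s2 <- random_smooth_spectrum()
    a <- stats::runif(1, 0.1, 3); bb <- stats::runif(1, 0.1, 3)
    comb <- spectral_irradiance(s1$wavelengths_nm,
                                a * s1$values + bb * s2$values,
                                unit = "photon")
    expect_equal(integrate_band(comb, b$PAR),
                 a * integrate_band(s1, b$PAR) +
                   bb * integrate_band(s2, b$PAR), tolerance = 1e-10)
    expect_equal(integrate_band(s1, b$UVB) + integrate_band(s1, b$UVA),
                 integrate_band(s1, uv), tolerance = 1e-9)
  }
})

test_that("extract band summaries: constants, ramps and normalisation", {
  g <- seq(190, 900, 1)
  flat <- absorbance_spectrum(g, rep(0.5, length(g)))
  sm <- extract_band_summary(flat)
  expect_equal(sm$A375, 0.5)
  expect_equal(sm$mean_UVB, 0.5)
  expect_equal(sm$mean_UVA, 0.5)
  expect_equal(sm$mean_UV, 0.5)

  # linear ramp: band mean equals the value at the band midpoint
  ramp <- absorbance_spectrum(g, 0.001 * g)
  expect_equal(extract_band_summary(ramp)$mean_UVA, 0.001 * 357.5)

  unit <- absorbance_spectrum(g, rep(1, length(g)), dilution = 2,
                              volume_ml = 3, fresh_weight_g = 0.05)
  expect_equal(extract_band_summary(unit)$mean_UV_norm, 120)
  bad <- absorbance_spectrum(g, rep(1, length(g)), dilution = 2,
                             volume_ml = 3, fresh_weight_g = 0)
  expect_error(extract_band_summary(bad), "fresh weight")
  expect_warning(absorbance_spectrum(g, rep(2.5, length(g))),
                 "absorbance > 2")
})
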