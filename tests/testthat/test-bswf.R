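# Weighting functions, effective doses and the red:far-red ratio.

# independently coded raw forms, used only as oracles
.oracle_pg_raw <- function(l)
  exp(4.688272 * exp(-exp(0.1703411 * (l - 307.867) / 1.15)) +
        ((390 - l) / 121.7557 - 4.183832))
.oracle_gen_raw <- function(l)
  2.618 * (1 - (l / 313.3)^2) * exp(-(l - 300) / 31.08)

test_that("PG weight: normalization anchor, shoulder value, domain cutoff", {
  pg <- bswf_pg()
  expect_equal(bswf_weight(pg, 300), 1, tolerance = 1e-12)
  # raw value at 390 nm ~ 0.0152
  raw390 <- bswf_weight(pg, 390) * .oracle_pg_raw(300)
  expect_equal(raw390, 0.0152, tolerance = 1e-3 / 0.0152)
  expect_identical(bswf_weight(pg, 395), 0)
  expect_identical(bswf_weight(pg, c(240, 400, 900)), c(0, 0, 0))
})

test_that("GEN(G) weight: anchor, boundary zero, 280/300 ratio", {
  gg <- bswf_gen_g()
  expect_equal(bswf_weight(gg, 300), 1, tolerance = 1e-12)
  expect_equal(bswf_weight(gg, 313.3), 0, tolerance = 1e-12)
  expect_identical(bswf_weight(gg, 320), 0)
  expect_equal(bswf_weight(gg, 280),
               .oracle_gen_raw(280) / .oracle_gen_raw(300),
               tolerance = 1e-10)
  expect_equal(bswf_weight(gg, 280), 4.61, tolerance = 0.05 / 4.61)
})

test_that("tabulated weights interpolate linearly and vanish outside", {
  nodes <- data.frame(lambda_nm = c(300, 310, 320),
                      weight = c(1.0, 0.2, 0.6))
  b <- bswf("toy", nodes = nodes, domain_nm = c(300, 320))
  expect_equal(bswf_weight(b, 310), 0.2)
  expect_equal(bswf_weight(b, 315), 0.4)   # midpoint of 0.2 and 0.6
  expect_identical(bswf_weight(b, 299), 0)
  expect_identical(bswf_weight(b, 321), 0)
  expect_error(bswf("bad", nodes = data.frame(l = c(310, 300),
                                              w = c(1, 1)),
                    domain_nm = c(300, 310)), "strictly increasing")
})

test_that("every registered BSWF is normalised, non-negative on a fine scan", {
  for (b in bswf_registry()) {
    expect_equal(bswf_weight(b, b$normalization_nm), 1, tolerance = 1e-12)
    scan <- seq(b$domain_nm[1], b$domain_nm[2], by = 0.1)
    expect_true(all(bswf_weight(b, scan) >= 0))
  }
})

test_that("effective dose: zero case, linearity, flat-spectrum oracle", {
  reg <- bswf_registry()
  # spectrum confined to >= 400 nm vs PG: zero dose
  s_par <- flat_spectrum(1, lo = 400, hi = 900)
  expect_equal(effective_dose(s_par, reg$PG)$dose, 0)
  s <- flat_spectrum(1)
  for (b in reg) {
    d1 <- effective_dose(s, b)$dose
    s2 <- s; s2$values <- 2 * s2$values
    expect_equal(effective_dose(s2, b)$dose, 2 * d1, tolerance = 1e-12)
    # oracle: 0.01 nm Riemann (trapezoid) sum of the weight function over
    # the integrated range
    lo <- max(b$domain_nm[1], 280); hi <- min(b$domain_nm[2], 900)
    gg <- seq(lo, hi, by = 0.01)
    w <- bswf_weight(b, gg)
    riemann <- sum(diff(gg) * (w[-1] + w[-length(w)])) / 2
    expect_equal(d1, riemann, tolerance = 1e-4)
  }
  expect_error(effective_dose(spectral_irradiance(c(300, 400), c(1, 1),
                                                  unit = "energy"),
                              reg$PG), "photon units")
})

test_that("effective dose is invariant to sub-nm resampling", {
  set.seed(7)
  s <- random_smooth_spectrum()
  pg <- bswf_pg()
  base <- effective_dose(s, pg)$dose
  for (step in c(0.25, 1)) {
    rs <- resample_spectrum(s, seq(280, 900, step))
    expect_equal(effective_dose(rs, pg)$dose, base, tolerance = 1e-4)
  }
})

test_that("doses of a UV-B-confined spectrum are bounded by weight extremes", {
  g <- seq(280, 900, 0.5)
  v <- ifelse(g < 315, exp(-((g - 305) / 6)^2), 0)
  s <- spectral_irradiance(g, v, unit = "photon")
  uvb <- integrate_band(s, canonical_bands()$UVB)
  support <- seq(280, 314.999, 0.01)
  for (b in list(bswf_pg(), bswf_gen_g())) {
    w <- bswf_weight(b, support)
    dose <- effective_dose(s, b)$dose
    expect_gte(dose, min(w) * uvb)
    expect_lte(dose, max(w) * uvb)
  }
})

test_that("red:far-red ratio: flat unity, area ratio, undefined case", {
  expect_equal(red_far_red_ratio(flat_spectrum(1)), 1, tolerance = 1e-12)
  g <- seq(280, 900, 0.5)
  v <- ifelse(g >= 650 & g < 670, 10, ifelse(g >= 720 & g < 740, 5, 1))
  s <- spectral_irradiance(g, v, unit = "photon")
  expect_equal(red_far_red_ratio(s), 2, tolerance = 1e-12)
  v0 <- ifelse(g >= 700, 0, 1)
  expect_error(red_far_red_ratio(spectral_irradiance(g, v0,
                                                     unit = "photon")),
               "undefined R:FR")
})

test_that("dose table carries the full quantity set per spectrum", {
  s <- flat_spectrum(1, stand = "S1", doy = 115, position = "shade",
                     point = "P1")
  tab <- dose_table(list(s))
  expect_setequal(names(tab), c("stand", "doy", "position", "point",
                                "PPFD", "UVB", "UVA", "PG", "FLAV",
                                "GEN_G", "R_FR"))
  expect_equal(tab$PPFD, 300)
  expect_equal(tab$UVA, 85)
})
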