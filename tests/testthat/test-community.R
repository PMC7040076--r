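# Community-weighted means and the per-date group comparisons.

test_that("CWM: weighted mean, single species, renormalisation", {
  tv <- toy_survey()
  # abundances {A: 0.6, B: 0.4}, species means {A: 1, B: 2} -> 1.4
  expect_equal(community_weighted_mean(tv$records, tv$abundances,
                                       "S1", "P1", 100), 1.4)

  # a single measured species gives that species' mean regardless of p
  r1 <- tv$records[tv$records$species == "A", ]
  expect_equal(community_weighted_mean(r1, tv$abundances,
                                       "S1", "P1", 100), 1)

  # unmeasured species C: weights renormalised to 0.625 / 0.375 -> 1.375
  ab3 <- data.frame(stand = "S1", point = "P1",
                    species = c("A", "B", "C"),
                    rel_abundance = c(0.5, 0.3, 0.2))
  expect_equal(community_weighted_mean(tv$records, ab3,
                                       "S1", "P1", 100), 1.375)

  abX <- data.frame(stand = "S1", point = "P1", species = "Z",
                    rel_abundance = 1)
  expect_error(community_weighted_mean(tv$records, abX, "S1", "P1", 100),
               "no overlap")
})

test_that("CWM bounds, equal-abundance and record-duplication invariance", {
  set.seed(21)
  for (i in 1:50) {
    n_sp <- sample(2:8, 1)
    sp <- paste0("s", seq_len(n_sp))
    recs <- do.call(rbind, lapply(sp, function(s) data.frame(
      plant_id = paste0(s, 1:3), species = s, stand = "S", point = "P",
      doy = 1, year = 2015L, leaf_side = "adaxial", leaf_age = "mature",
      iflav = stats::runif(3, 0, 3))))
    w <- stats::rgamma(n_sp, 2); w <- w / sum(w)
    ab <- data.frame(stand = "S", point = "P", species = sp,
                     rel_abundance = w)
    cwm <- community_weighted_mean(recs, ab, "S", "P", 1)
    sp_means <- tapply(recs$iflav, recs$species, mean)
    expect_gte(cwm, min(sp_means) - 1e-12)
    expect_lte(cwm, max(sp_means) + 1e-12)
    # equal abundances: unweighted mean of species means
    ab_eq <- transform(ab, rel_abundance = 1 / n_sp)
    expect_equal(community_weighted_mean(recs, ab_eq, "S", "P", 1),
                 mean(sp_means), tolerance = 1e-12)
    # duplicating the record set leaves species means, hence the CWM, alone
    expect_equal(community_weighted_mean(rbind(recs, recs), ab, "S", "P", 1),
                 cwm, tolerance = 1e-12)
  }
})

test_that("record and abundance validation", {
  tv <- toy_survey()
  expect_silent(validate_iflav_records(tv$records))
  bad <- tv$records; bad$iflav[1] <- -1
  expect_error(validate_iflav_records(bad), "iflav must be >= 0")
  high <- tv$records; high$iflav[1] <- 3.5
  expect_warning(validate_iflav_records(high), "outside the usual range")
  expect_silent(validate_abundances(tv$abundances))
  ab_bad <- tv$abundances; ab_bad$rel_abundance <- c(0.6, 0.5)
  expect_error(validate_abundances(ab_bad), "sum to 1")
})

test_that("per-DOY ANOVA: identical groups, separation, degenerate rows", {
  mk <- function(doy, stand, vals) data.frame(
    plant_id = paste(stand, doy, seq_along(vals)), species = "s",
    stand = stand, point = "P", doy = doy, year = 2015L,
    leaf_side = "adaxial", leaf_age = "mature", iflav = vals)

  recs <- rbind(mk(1, "A", c(1, 2, 3)), mk(1, "B", c(1, 2, 3)))
  res <- anova_by_doy(recs)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  set.seed(5)
  hits <- replicate(30, {
    r <- rbind(mk(1, "A", stats::rnorm(20, 0)),
               mk(1, "B", stats::rnorm(20, 5)))
    anova_by_doy(r)$p < 0.001
  })
  expect_gte(mean(hits), 0.99)

  # zero within-group variance with equal means: null row with reason
  degen <- rbind(mk(2, "A", c(1, 1, 1)), mk(2, "B", c(1, 1, 1)))
  resd <- anova_by_doy(degen)
  expect_true(is.na(resd$F))
  expect_false(is.na(resd$reason))

  # a DOY with a single group: null row
  res1 <- anova_by_doy(mk(3, "A", c(1, 2, 3)))
  expect_true(is.na(res1$F))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(9)
  mk <- function(stand, vals) data.frame(
    plant_id = paste(stand, seq_along(vals)), species = "s",
    stand = stand, point = "P", doy = 1, year = 2015L,
    leaf_side = "adaxial", leaf_age = "mature", iflav = vals)
  for (i in 1:10) {
    x <- stats::rnorm(12); y <- stats::rnorm(15, 0.5)
    f <- anova_by_doy(rbind(mk("A", x), mk("B", y)))$F
    t <- stats::t.test(x, y, var.equal = TRUE)$statistic
    expect_equal(f, unname(t^2), tolerance = 1e-9)
  }
})

test_that("two-sample comparisons: t, exact Wilcoxon, degenerate ties", {
  x <- c(1.2, 1.5, 1.9, 2.2)
  res <- two_sample_compare(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # enumeration oracle: all C(4,2)=6 rank splits of {1,2} vs {3,4}
  expect_equal(two_sample_compare(c(1, 2), c(3, 4), method = "wilcoxon",
                                  alternative = "less")$p, 1 / 6)
  expect_equal(two_sample_compare(c(1, 2), c(3, 4),
                                  method = "wilcoxon")$p, 1 / 3)

  expect_message(res_tied <- two_sample_compare(rep(2, 5), rep(2, 4)),
                 "tied")
  expect_equal(res_tied$p, 1)

  set.seed(13)
  hits <- replicate(60, {
    a <- stats::rnorm(30); b <- stats::rnorm(30, 2)
    two_sample_compare(a, b)$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
})
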