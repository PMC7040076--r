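# Leaf-trait survey data model: community-weighted means of the flavonol
# index and the per-date group comparisons.

#' Validate a flavonol-index record table
#'
#' One row per plant × leaf side × DOY: columns `plant_id`, `species`,
#' `stand`, `point`, `doy`, `year`, `leaf_side` (adaxial|abaxial),
#' `leaf_age` (new|mature|overwintered), `iflav` (dimensionless, >= 0),
#' optional `anth` and `chl` pass-through columns. Values of `iflav`
#' above 3 are outside the optical clip's usual range and are flagged
#' with a warning, not rejected.
#'
#' @param records data.frame.
#' @return the validated data.frame (invisibly the same object).
#' @export
validate_iflav_records <- function(records) {
  need <- c("plant_id", "species", "stand", "point", "doy", "leaf_side",
            "iflav")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(records$iflav < 0, na.rm = TRUE)) stop("iflav must be >= 0")
  if (!all(records$leaf_side %in% c("adaxial", "abaxial")))
    stop("leaf_side must be adaxial or abaxial")
  n_high <- sum(records$iflav > 3, na.rm = TRUE)
  if (n_high)
    warning(n_high, " record(s) with iflav > 3 (outside the usual range)")
  records
}

#' Validate a species relative-abundance table
#'
#' Columns `stand`, `point`, `species`, `rel_abundance`; abundances are
#' non-negative and sum to 1 (±1e-9) within each stand × point.
#'
#' @param abundances data.frame.
#' @return the validated data.frame.
#' @export
validate_abundances <- function(abundances) {
  need <- c("stand", "point", "species", "rel_abundance")
  miss <- setdiff(need, names(abundances))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(abundances$rel_abundance < 0)) stop("abundances must be >= 0")
  sums <- stats::aggregate(rel_abundance ~ stand + point, abundances, sum)
  if (any(abs(sums$rel_abundance - 1) > 1e-9))
    stop("abundances must sum to 1 per stand x point")
  abundances
}

#' Community-weighted mean flavonol index
#'
#' CWM for one stand × point × DOY × leaf side: species means of `iflav`
#' are computed from the records at that point and date, then weighted by
#' the point's relative abundances renormalised over the species actually
#' measured there on that date (so the CWM remains a proper mean when some
#' species present in the abundance survey were not measured).
#'
#' @param records flavonol-index records ([validate_iflav_records()]).
#' @param abundances abundance table ([validate_abundances()]).
#' @param stand,point,doy cell selectors.
#' @param side leaf side, default `"adaxial"`.
#' @return the CWM (scalar).
#' @export
community_weighted_mean <- function(records, abundances, stand, point, doy,
                                    side = "adaxial") {
  r <- records[records$stand == stand & records$point == point &
                 records$doy == doy & records$leaf_side == side, ]
  if (!nrow(r)) stop("no records for this stand/point/doy/side")
  sp_means <- tapply(r$iflav, r$species, mean)
  a <- abundances[abundances$stand == stand & abundances$point == point, ]
  common <- intersect(names(sp_means), a$species)
  if (!length(common))
    stop("no overlap between measured species and the abundance table")
  w <- a$rel_abundance[match(common, a$species)]
  if (sum(w) <= 0) stop("measured species all have zero abundance")
  w <- w / sum(w)
  sum(w * sp_means[common])
}

#' CWM table over all surveyed cells
#'
#' @inheritParams community_weighted_mean
#' @return data.frame with one row per stand × point × DOY present in the
#'   records: `stand`, `point`, `doy`, `cwm`.
#' @export
cwm_table <- function(records, abundances, side = "adaxial") {
  r <- records[records$leaf_side == side, ]
  cells <- unique(r[, c("stand", "point", "doy")])
  cells$cwm <- mapply(function(s, p, d)
    community_weighted_mean(records, abundances, s, p, d, side),
    cells$stand, cells$point, cells$doy)
  rownames(cells) <- NULL
  cells
}

#' One-way ANOVA of the flavonol index per day of year
#'
#' Fixed-effects one-way ANOVA of `iflav` across groups (default: stands)
#' run separately for each DOY. Days with fewer than two groups having at
#' least two observations, or with zero residual variance, yield a row of
#' `NA` statistics and a reason code rather than an error.
#'
#' @param records flavonol-index records.
#' @param group name of the grouping column, default `"stand"`.
#' @return data.frame: doy, F, df1, df2, p, reason.
#' @export
anova_by_doy <- function(records, group = "stand") {
  rows <- lapply(sort(unique(records$doy)), function(d) {
    r <- records[records$doy == d, ]
    counts <- table(r[[group]])
    counts <- counts[counts >= 2]
    na_row <- function(reason)
      data.frame(doy = d, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                 p = NA_real_, reason = reason, stringsAsFactors = FALSE)
    if (length(counts) < 2) return(na_row("fewer than 2 groups with n >= 2"))
    r <- r[r[[group]] %in% names(counts), ]
    g <- factor(r[[group]])
    within_ss <- sum(tapply(r$iflav, g, function(x) sum((x - mean(x))^2)))
    if (within_ss == 0 && stats::sd(r$iflav) == 0)
      return(na_row("zero residual variance"))
    fit <- stats::aov(r$iflav ~ g)
    an <- stats::anova(fit)
    if (!is.finite(an$`F value`[1])) return(na_row("zero residual variance"))
    data.frame(doy = d, F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
               p = an$`Pr(>F)`[1], reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample comparison of flavonol index groups
#'
#' Student's two-sample t test (Welch by default; pooled variance on
#' request) or the Wilcoxon rank-sum test — exact enumeration for small
#' samples without ties, normal approximation with tie correction
#' otherwise — as used for adaxial vs abaxial leaf-side comparisons. If
#' every value is tied across both samples the comparison is vacuous and
#' p = 1 is returned by convention.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param method `"t"` or `"wilcoxon"`.
#' @param pooled for `method = "t"`, use the pooled-variance statistic
#'   instead of Welch.
#' @param paired treat samples as paired (requires equal lengths); off by
#'   default, matching the two-sample convention.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `statistic`, `p`, `method`.
#' @export
two_sample_compare <- function(x, y, method = c("t", "wilcoxon"),
                               pooled = FALSE, paired = FALSE,
                               alternative = "two.sided") {
  method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per sample")
  if (stats::sd(c(x, y)) == 0) {
    message("all values tied across both samples; p = 1 by convention")
    return(list(statistic = 0, p = 1, method = method))
  }
  if (method == "t") {
    ht <- stats::t.test(x, y, var.equal = pooled, paired = paired,
                        alternative = alternative)
  } else {
    n_tot <- length(x) + length(y)
    ht <- stats::wilcox.test(x, y, paired = paired,
                             alternative = alternative,
                             exact = n_tot <= 20 &&
                               !anyDuplicated(c(x, y)),
                             correct = FALSE)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, method = method)
}
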