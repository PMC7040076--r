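# Local-regression trend curves with pointwise confidence intervals,
# CI-overlap comparison of trends, and Pearson correlations with the
# significance brackets used in the irradiance-correlation tables.

# tricube weights for x around x0; alpha <= 1 -> span over ceil(alpha*n)
# nearest points (bandwidth = largest included distance); alpha > 1 ->
# bandwidth inflated to alpha * max distance over all points
.tricube_weights <- function(x, x0, alpha) {
  d <- abs(x - x0)
  n <- length(x)
  if (alpha <= 1) {
    q <- ceiling(alpha * n)
    h <- sort(d)[q]
  } else {
    h <- alpha * max(d)
  }
  if (h <= 0) return(as.numeric(d == 0))
  w <- (1 - pmin(d / h, 1)^3)^3
  w
}

# equivalent-kernel row l(x0)': fit = l'y for a local polynomial of
# degree `degree` with weights w
.loess_l_row <- function(x, x0, w, degree) {
  keep <- w > 0
  if (sum(keep) < degree + 2)
    stop("too few points with positive weight: increase span")
  X <- outer(x[keep] - x0, 0:degree, `^`)
  W <- w[keep]
  XtW <- t(X * W)
  A <- XtW %*% X
  l_keep <- solve(A, XtW)[1, ]
  l <- numeric(length(x))
  l[keep] <- l_keep
  l
}

#' Local-regression trend with pointwise 95% confidence intervals
#'
#' Fits a loess-style local polynomial trend: at each evaluation point a
#' weighted least-squares polynomial of degree `degree` is fitted with
#' tricube weights over the `ceiling(span * n)` nearest observations
#' (for `span` <= 1), or over all observations with the bandwidth
#' inflated to `span` times the maximum distance (for `span` > 1, the
#' convention used when a trend is deliberately over-smoothed).
#'
#' Standard errors come from the equivalent kernel: the fit at x0 is
#' l(x0)'y, so SE(x0) = sigma_hat * ||l(x0)||, with sigma_hat^2 estimated
#' from the residuals using the trace-based degrees of freedom
#' n - 2 tr(L) + tr(L'L) of the smoother matrix L. The pointwise 95% CI
#' is fit ± t(0.975, df) * SE.
#'
#' @param x,y observations (e.g. DOY and flavonol index).
#' @param span the smoothing parameter alpha; default 1.
#' @param degree local polynomial degree; default 2.
#' @param grid evaluation grid; default the integer sequence spanning
#'   `x` (integer DOYs).
#' @param level CI level, default 0.95.
#' @return an object of class `loess_fit`: data.frame `curve` with
#'   columns `x`, `fit`, `se`, `lower`, `upper`; plus `span`, `degree`,
#'   `df`, `sigma`.
#' @export
loess_fit <- function(x, y, span = 1, degree = 2, grid = NULL,
                      level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  n <- length(x)
  if (span <= 0) stop("span must be > 0")
  if (n < degree + 2) stop("need at least degree + 2 observations")
  if (span <= 1 && ceiling(span * n) < degree + 2)
    stop("span * n below degree + 2 effective points")
  if (is.null(grid)) grid <- seq(floor(min(x)), ceiling(max(x)))
  # smoother matrix over the data points, for residual df
  L <- t(vapply(x, function(x0)
    .loess_l_row(x, x0, .tricube_weights(x, x0, span), degree),
    numeric(n)))
  fitted_data <- as.vector(L %*% y)
  res <- y - fitted_data
  df <- n - 2 * sum(diag(L)) + sum(L * L)
  df <- max(df, 1)
  sigma <- sqrt(sum(res^2) / df)
  rows <- lapply(grid, function(x0) {
    l <- .loess_l_row(x, x0, .tricube_weights(x, x0, span), degree)
    data.frame(x = x0, fit = sum(l * y), se = sigma * sqrt(sum(l^2)))
  })
  curve <- do.call(rbind, rows)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  curve$lower <- curve$fit - tq * curve$se
  curve$upper <- curve$fit + tq * curve$se
  structure(list(curve = curve, span = span, degree = degree, df = df,
                 sigma = sigma, level = level, n = n),
            class = "loess_fit")
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf(
    "<loess_fit> n=%d span=%g degree=%d sigma=%.4g df=%.1f, %d grid points\n",
    x$n, x$span, x$degree, x$sigma, x$df, nrow(x$curve)))
  invisible(x)
}

#' Confidence-interval overlap between two trend fits
#'
#' Two trends are declared different at an evaluation point when their
#' pointwise CIs do not overlap: lowerA > upperB or lowerB > upperA
#' (strict inequalities). Contiguous runs of non-overlap are reported as
#' intervals on the shared grid (e.g. DOY windows in which two stands'
#' flavonol trends separate).
#'
#' @param fit_a,fit_b [loess_fit()] objects evaluated on the same grid.
#' @return list with `overlap` (logical per grid point, TRUE = CIs
#'   overlap) and `non_overlap_intervals`, a data.frame of `from`/`to`
#'   grid values for each maximal run of non-overlap.
#' @export
ci_overlap <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "loess_fit"), inherits(fit_b, "loess_fit"))
  ga <- fit_a$curve$x; gb <- fit_b$curve$x
  if (length(ga) != length(gb) || any(ga != gb))
    stop("fits evaluated on different grids")
  sep <- fit_a$curve$lower > fit_b$curve$upper |
    fit_b$curve$lower > fit_a$curve$upper
  runs <- rle(sep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  idx <- which(runs$values)
  intervals <- data.frame(from = ga[starts[idx]], to = ga[ends[idx]])
  list(overlap = !sep, non_overlap_intervals = intervals)
}

#' Significance bracket for a p-value
#'
#' The bracket convention of the irradiance-correlation tables:
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p < 0.05 (strict),
#' `ns` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of brackets.
#' @export
significance_bracket <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Pearson correlation with t test and significance bracket
#'
#' Sample Pearson correlation r, the test statistic
#' t = r sqrt(n-2) / sqrt(1-r^2), the two-sided p from the t distribution
#' on n-2 df, and the significance bracket.
#'
#' @param x,y paired numeric vectors, n >= 3, both with positive
#'   variance.
#' @return one-row data.frame: r, n, t, p, bracket.
#' @export
pearson_r_with_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(r = NA_real_, n = n, t = NA_real_, p = NA_real_,
                      bracket = NA_character_, stringsAsFactors = FALSE))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  correlation_test_from_r(r, n)
}

#' @describeIn pearson_r_with_test test and bracket from a correlation
#'   coefficient and sample size alone (as printed in a correlation
#'   table).
#' @param r correlation coefficient.
#' @param n number of pairs.
#' @export
correlation_test_from_r <- function(r, n) {
  if (abs(r) >= 1) {
    t <- sign(r) * Inf; p <- 0
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  data.frame(r = r, n = n, t = t, p = p,
             bracket = significance_bracket(p), stringsAsFactors = FALSE)
}

#' Stand × quantity × position correlation table
#'
#' Correlates the mean flavonol index per stand × DOY × point against
#' each spectral quantity (waveband irradiances, effective doses, R:FR)
#' at each understorey position, pooling the stand's point × DOY cells as
#' pairs — the shape of the published irradiance-correlation table.
#'
#' @param doses tidy dose table ([dose_table()]): one row per
#'   stand × doy × position × point with quantity columns.
#' @param iflav_means data.frame with `stand`, `point`, `doy`, `iflav`
#'   (mean index or CWM per cell).
#' @param quantities quantity columns to correlate; default all of PPFD,
#'   UVB, UVA, PG, FLAV, GEN_G, R_FR present in `doses`.
#' @param positions positions to include; default sunfleck, leaf, shade.
#' @return data.frame: stand, quantity, position, r, n, t, p, bracket.
#' @export
correlation_table <- function(doses, iflav_means,
                              quantities = intersect(
                                c("UVB", "UVA", "PPFD", "FLAV", "PG",
                                  "GEN_G", "R_FR"), names(doses)),
                              positions = c("sunfleck", "leaf", "shade")) {
  rows <- list()
  for (st in unique(doses$stand)) {
    for (q in quantities) {
      for (pos in positions) {
        d <- doses[doses$stand == st & doses$position == pos,
                   c("point", "doy", q)]
        m <- merge(d, iflav_means[iflav_means$stand == st, ],
                   by = c("point", "doy"))
        res <- if (nrow(m) >= 3 && stats::sd(m[[q]]) > 0 &&
                   stats::sd(m$iflav) > 0)
          pearson_r_with_test(m[[q]], m$iflav)
        else data.frame(r = NA_real_, n = nrow(m), t = NA_real_,
                        p = NA_real_, bracket = NA_character_,
                        stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(stand = st, quantity = q, position = pos,
                     stringsAsFactors = FALSE), res)
      }
    }
  }
  do.call(rbind, rows)
}
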