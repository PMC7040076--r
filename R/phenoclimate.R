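# Thermal-season segmentation of a daily weather series and the
# growing-season covariates correlated with the flavonol index.

#' Daily weather series
#'
#' @param date vector of `Date`s, contiguous daily.
#' @param t_mean,t_min,t_max daily mean/min/max air temperature (°C);
#'   `t_min <= t_mean <= t_max` is enforced.
#' @param snow_depth_cm snow depth (cm), >= 0, may be `NA`.
#' @return a data.frame of class `daily_weather` with a `doy` column.
#' @export
daily_weather <- function(date, t_mean, t_min = t_mean, t_max = t_mean,
                          snow_depth_cm = NA_real_) {
  date <- as.Date(date)
  if (any(diff(as.integer(date)) != 1L))
    stop("dates must be contiguous daily")
  if (any(t_min > t_mean + 1e-9) || any(t_mean > t_max + 1e-9))
    stop("need t_min <= t_mean <= t_max")
  if (any(snow_depth_cm < 0, na.rm = TRUE))
    stop("snow depth must be >= 0")
  out <- data.frame(date = date, doy = as.integer(format(date, "%j")),
                    t_mean = t_mean, t_min = t_min, t_max = t_max,
                    snow_depth_cm = snow_depth_cm)
  class(out) <- c("daily_weather", "data.frame")
  out
}

# first index >= from at which `cond` (logical vector) holds for >= n
# consecutive days; NA if never
.first_run <- function(cond, n, from = 1L) {
  cond[is.na(cond)] <- FALSE
  len <- length(cond)
  run <- 0L
  for (i in seq(from, len)) {
    run <- if (cond[i]) run + 1L else 0L
    if (run >= n) return(i - n + 1L)
  }
  NA_integer_
}

#' Thermal-season segmentation
#'
#' Seasons are defined by the mean daily air temperature being
#' continuously above 0 °C (spring), above +10 °C (summer), below +10 °C
#' (autumn) or below 0 °C (winter). "Continuously" is operationalised as
#' the first run of at least `N` consecutive days meeting the condition,
#' each season searched from the previous season's start onward. A season
#' whose condition is never met is reported as `NA`, not an error.
#'
#' @param weather a [daily_weather()] covering at least one year.
#' @param N run length (days) required for a season to start; default 5.
#' @return an object of class `season_segmentation`: list with
#'   `spring`, `summer`, `autumn`, `winter` start indices (positions in
#'   the series; equal to DOY when the series starts on 1 January), the
#'   run length `N`, and `season`, a per-day season factor.
#' @export
segment_thermal_seasons <- function(weather, N = 5) {
  stopifnot(inherits(weather, "daily_weather"))
  t <- weather$t_mean
  spring <- .first_run(t > 0, N)
  summer <- if (!is.na(spring)) .first_run(t > 10, N, from = spring)
            else .first_run(t > 10, N)
  autumn <- if (!is.na(summer)) .first_run(t < 10, N, from = summer)
            else NA_integer_
  winter <- if (!is.na(autumn)) .first_run(t < 0, N, from = autumn)
            else .first_run(t < 0, N, from = max(1L, summer, na.rm = TRUE))
  starts <- c(spring = spring, summer = summer, autumn = autumn,
              winter = winter)
  season <- rep(NA_character_, nrow(weather))
  bounds <- sort(starts[!is.na(starts)])
  if (length(bounds)) {
    if (bounds[1] > 1) season[seq_len(bounds[1] - 1)] <- "winter"
    for (k in seq_along(bounds)) {
      to <- if (k < length(bounds)) bounds[k + 1] - 1 else nrow(weather)
      season[bounds[k]:to] <- names(bounds)[k]
    }
  } else season[] <- "winter"
  structure(list(spring = spring, summer = summer, autumn = autumn,
                 winter = winter, N = N,
                 season = factor(season, levels = c("winter", "spring",
                                                    "summer", "autumn"))),
            class = "season_segmentation")
}

#' @export
print.season_segmentation <- function(x, ...) {
  cat(sprintf("<season_segmentation> N=%d  spring=%s summer=%s autumn=%s winter=%s\n",
              x$N, x$spring, x$summer, x$autumn, x$winter))
  invisible(x)
}

#' Growing-season weather covariates for a day of year
#'
#' Computes, for a given index into the weather series, the covariates
#' used against mean flavonol index: days post snowmelt, days prior to the
#' first marked snowfall, days from the beginning of the thermal growing
#' season, and the effective temperature sum.
#'
#' The thermal growing season starts at the first run of at least `N`
#' days with `t_mean` strictly above `T_base`; the effective temperature
#' sum at day d is the cumulative `max(0, t_mean - T_base)` from that
#' start through d (°C·d). The snowmelt day is the first spring day on
#' which snow depth is 0 followed by at least `K` consecutive snow-free
#' days; the first marked snowfall is the first day at/after mid-year
#' with snow depth >= `s_min` persisting for at least `K` days.
#'
#' @param weather a [daily_weather()].
#' @param segmentation a [segment_thermal_seasons()] result for the same
#'   series.
#' @param doy index (day number within the series; equals DOY for a
#'   series starting 1 January).
#' @param T_base base temperature (°C) for the temperature sum and the
#'   growing-season threshold; default +5 °C.
#' @param K persistence (days) for snowmelt/snowfall detection; default 7.
#' @param s_min minimum depth (cm) counting as marked snowfall; default 1.
#' @return a one-row data.frame: `doy`, `days_post_snowmelt`,
#'   `days_prior_first_snowfall`, `days_from_growing_season_start`,
#'   `effective_temperature_sum`. Counters are `NA` where the defining
#'   event is absent or lies after `doy` in the series.
#' @export
growing_season_variables <- function(weather, segmentation, doy,
                                     T_base = 5, K = 7, s_min = 1) {
  stopifnot(inherits(weather, "daily_weather"))
  n <- nrow(weather)
  if (doy < 1 || doy > n) stop("doy outside series")
  t <- weather$t_mean
  gs_start <- .first_run(t > T_base, segmentation$N)
  ets <- 0
  gs_days <- NA_integer_
  if (!is.na(gs_start) && doy >= gs_start) {
    ets <- sum(pmax(0, t[gs_start:doy] - T_base))
    gs_days <- doy - gs_start
  }
  snow <- weather$snow_depth_cm
  melt <- .first_run(!is.na(snow) & snow == 0, K)
  post_melt <- if (!is.na(melt) && doy >= melt) doy - melt else NA_integer_
  from_fall <- if (!is.na(segmentation$autumn)) segmentation$autumn
               else min(n, n %/% 2L)
  fall <- .first_run(!is.na(snow) & snow >= s_min, K, from = from_fall)
  prior_fall <- if (!is.na(fall) && fall >= doy) fall - doy else NA_integer_
  data.frame(doy = doy, days_post_snowmelt = post_melt,
             days_prior_first_snowfall = prior_fall,
             days_from_growing_season_start = gs_days,
             effective_temperature_sum = ets)
}

#' Correlate mean flavonol index with weather covariates
#'
#' Pearson correlation of a per-DOY mean flavonol index series against
#' each weather covariate, via [pearson_r_with_test()]. Covariates (or an
#' index series) with zero variance yield an `NA` row rather than an
#' error.
#'
#' @param iflav_by_doy data.frame with columns `doy` and `iflav`
#'   (mean index per DOY).
#' @param covariates data.frame with column `doy` plus one column per
#'   covariate, as stacked rows of [growing_season_variables()].
#' @return data.frame: covariate, n, r, t, p, bracket.
#' @export
correlate_weather_iflav <- function(iflav_by_doy, covariates) {
  merged <- merge(iflav_by_doy, covariates, by = "doy")
  vars <- setdiff(names(covariates), "doy")
  rows <- lapply(vars, function(v) {
    ok <- stats::complete.cases(merged[, c("iflav", v)])
    x <- merged[[v]][ok]; y <- merged$iflav[ok]
    res <- if (sum(ok) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0)
      pearson_r_with_test(x, y)
    else data.frame(r = NA_real_, n = sum(ok), t = NA_real_, p = NA_real_,
                    bracket = NA_character_, stringsAsFactors = FALSE)
    cbind(data.frame(covariate = v, stringsAsFactors = FALSE), res)
  })
  do.call(rbind, rows)
}
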