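#' Fit a first-order harmonic curve to an NDVI time series
#'
#' Least squares of ndvi(t) = a0 + a1 cos(2 pi t / 365) + b1 sin(2 pi t /
#' 365) over Julian days 1-212 (January through end of July). The fitted
#' wave is summarised by its amplitude sqrt(a1^2 + b1^2) and phase, and by
#' its closed-form extrema a0 -/+ amplitude — the modelled seasonal minimum
#' and maximum NDVI. Missing (cloud-masked) observations are simply omitted.
#'
#' @param ts Tibble for one pixel-year: columns `day` (Julian day, 1-212)
#'   and `ndvi` (dimensionless, within [-1, 1]); at least 8 non-missing
#'   observations spanning at least 120 days.
#' @return One-row tibble of class data: `a0`, `a1`, `b1`, `amplitude`,
#'   `phase` (radians), `fitted_min`, `fitted_max`, `rmse`, `n_obs`.
#' @export
fit_harmonic <- function(ts) {
  stopifnot_cols(ts, c("day", "ndvi"), "ndvi series")
  s <- ts %>% filter(!is.na(.data$ndvi))
  if (any(s$day < 1 | s$day > 212)) abort("days must lie in 1..212")
  if (any(abs(s$ndvi) > 1)) abort("NDVI must lie in [-1, 1]")
  if (nrow(s) < 8) abort("need at least 8 non-missing NDVI observations")
  if (diff(range(s$day)) < 120) abort("observations must span at least 120 days")
  om <- 2 * pi / 365
  X <- cbind(1, cos(om * s$day), sin(om * s$day))
  cf <- qr.solve(X, s$ndvi)
  fitted <- as.numeric(X %*% cf)
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  tibble(a0 = cf[1], a1 = cf[2], b1 = cf[3],
         amplitude = amp, phase = atan2(cf[3], cf[2]),
         fitted_min = cf[1] - amp, fitted_max = cf[1] + amp,
         rmse = sqrt(mean((s$ndvi - fitted)^2)), n_obs = nrow(s))
}

harmonic_value <- function(fit, day) {
  om <- 2 * pi / 365
  fit$a0 + fit$a1 * cos(om * day) + fit$b1 * sin(om * day)
}

#' Green-up date at the 50% NDVI threshold
#'
#' The NDVI50 threshold is the midpoint of the modelled seasonal range,
#' NDVI_min + 0.5 (NDVI_max - NDVI_min); the start-of-season day is the
#' first day in [0, 212] at which the fitted harmonic crosses that value
#' while increasing, solved in closed form for the single harmonic. A flat
#' fit (zero amplitude), or a window containing no rising crossing, is
#' flagged rather than dated.
#'
#' @param fit One-row tibble from [fit_harmonic()].
#' @return One-row tibble: `ndvi50`, `sos_day` (continuous day of year;
#'   `NA` when flagged), `flag` (`"ok"`, `"flat"`, or `"no_rising_crossing"`).
#' @export
ndvi50_date <- function(fit) {
  if (fit$amplitude <= 1e-12) {
    return(tibble(ndvi50 = fit$a0, sos_day = NA_real_, flag = "flat"))
  }
  ndvi50 <- fit$fitted_min + 0.5 * (fit$fitted_max - fit$fitted_min)
  om <- 2 * pi / 365
  # a0 + A cos(om t - phi) = ndvi50  =>  cos(om t - phi) = 0 on the rising
  # branch: om t - phi = -pi/2 + 2 pi k (derivative -A om sin(.) > 0).
  phi <- fit$phase
  t0 <- (phi - pi / 2) / om
  candidates <- t0 + 365 * (-2:2)
  candidates <- sort(candidates[candidates >= 0 & candidates <= 212])
  if (length(candidates) == 0) {
    return(tibble(ndvi50 = ndvi50, sos_day = NA_real_,
                  flag = "no_rising_crossing"))
  }
  tibble(ndvi50 = ndvi50, sos_day = candidates[1], flag = "ok")
}

#' Fit harmonics and date green-up for a pixel-year stack
#'
#' Convenience wrapper applying [fit_harmonic()] and [ndvi50_date()] to
#' every pixel-year of a long NDVI table; pixel-years whose fit fails its
#' preconditions are returned with an error flag instead of aborting the
#' stack.
#'
#' @param ndvi Long tibble: `pixel_id`, `year`, `day`, `ndvi`.
#' @return Tibble with one row per pixel-year: `pixel_id`, `year`, harmonic
#'   coefficients, `ndvi50`, `sos_day`, `flag`.
#' @export
phenology_dates <- function(ndvi) {
  stopifnot_cols(ndvi, c("pixel_id", "year", "day", "ndvi"), "ndvi stack")
  ndvi %>%
    group_by(.data$pixel_id, .data$year) %>%
    dplyr::group_modify(function(d, key) {
      fit <- try(fit_harmonic(d), silent = TRUE)
      if (inherits(fit, "try-error")) {
        return(tibble(a0 = NA_real_, amplitude = NA_real_,
                      ndvi50 = NA_real_, sos_day = NA_real_,
                      flag = "fit_failed"))
      }
      dt <- ndvi50_date(fit)
      tibble(a0 = fit$a0, amplitude = fit$amplitude,
             ndvi50 = dt$ndvi50, sos_day = dt$sos_day, flag = dt$flag)
    }) %>%
    ungroup()
}

#' Temperature sensitivity of green-up for one pixel
#'
#' Pearson correlation and OLS slope (alpha, days per degC) of the annual
#' start-of-season day on spring (MAM) mean temperature; negative alpha
#' means earlier green-up in warmer springs.
#'
#' @param dates Tibble with columns `year`, `sos_day` for one pixel.
#' @param temp Tibble with columns `year`, `value` (MAM temperature, degC).
#' @param min_years Minimum overlapping years (default 5).
#' @return One-row tibble: `r`, `alpha`, `n_years`, `flag`.
#' @export
pixel_sensitivity <- function(dates, temp, min_years = 5) {
  stopifnot_cols(dates, c("year", "sos_day"), "dates")
  stopifnot_cols(temp, c("year", "value"), "temp")
  m <- dplyr::inner_join(dates, temp, by = "year") %>%
    filter(!is.na(.data$sos_day), !is.na(.data$value))
  if (nrow(m) < min_years) {
    return(tibble(r = NA_real_, alpha = NA_real_, n_years = nrow(m),
                  flag = "insufficient overlap"))
  }
  if (stats::sd(m$value) == 0) {
    return(tibble(r = NA_real_, alpha = NA_real_, n_years = nrow(m),
                  flag = "constant temperature"))
  }
  if (stats::sd(m$sos_day) == 0) {
    return(tibble(r = 0, alpha = 0, n_years = nrow(m), flag = "constant sos"))
  }
  tibble(r = cor(m$sos_day, m$value),
         alpha = unname(coef(lm(sos_day ~ value, data = m))[2]),
         n_years = nrow(m), flag = "ok")
}

#' Sensitivity map over an NDVI pixel stack
#'
#' Applies [pixel_sensitivity()] to every pixel of a phenology-date table
#' against a common spring-temperature series (each 500-m pixel inherits
#' the seasonal mean of its enclosing grid cell).
#'
#' @param dates Tibble from [phenology_dates()] (needs `pixel_id`, `year`,
#'   `sos_day`).
#' @param temp Tibble with columns `year`, `value`.
#' @param min_years Passed to [pixel_sensitivity()].
#' @return Tibble with one row per pixel: `pixel_id`, `r`, `alpha`,
#'   `n_years`, `flag`.
#' @export
sensitivity_map <- function(dates, temp, min_years = 5) {
  stopifnot_cols(dates, c("pixel_id", "year", "sos_day"), "dates")
  dates %>%
    group_by(.data$pixel_id) %>%
    dplyr::group_modify(function(d, key) pixel_sensitivity(d, temp, min_years)) %>%
    ungroup()
}

#' Summarise pixel sensitivity by forest cover class
#'
#' Joins a per-pixel sensitivity map with a categorical cover raster
#' (co-registered: one class per pixel id) and summarises the distributions
#' of r and alpha per class. Pixels without a class are excluded and
#' counted.
#'
#' @param sens Tibble from [sensitivity_map()].
#' @param cover Tibble with columns `pixel_id`, `cover_class`.
#' @return List with `by_class` (per-class n, mean/quartiles of `r` and
#'   `alpha`) and `n_unclassified`.
#' @export
classify_and_summarize <- function(sens, cover) {
  stopifnot_cols(sens, c("pixel_id", "r", "alpha"), "sens")
  stopifnot_cols(cover, c("pixel_id", "cover_class"), "cover")
  joined <- left_join(sens, distinct(cover), by = "pixel_id")
  unclassified <- sum(is.na(joined$cover_class))
  by_class <- joined %>%
    filter(!is.na(.data$cover_class), !is.na(.data$r)) %>%
    group_by(.data$cover_class) %>%
    summarise(n = dplyr::n(),
              r_mean = mean(.data$r),
              r_q25 = quantile(.data$r, 0.25),
              r_median = median(.data$r),
              r_q75 = quantile(.data$r, 0.75),
              alpha_mean = mean(.data$alpha),
              alpha_q25 = quantile(.data$alpha, 0.25),
              alpha_median = median(.data$alpha),
              alpha_q75 = quantile(.data$alpha, 0.75),
              .groups = "drop")
  list(by_class = by_class, n_unclassified = unclassified)
}
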