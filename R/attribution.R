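#' Decadal trend and total change of an annual series
#'
#' Ordinary least-squares slope of value on year over the requested period,
#' reported per decade, with the total change over the period defined as
#' slope x span / 10 (span in years, e.g. 49 years for 1961-2010). This
#' convention reproduces printed total-warming figures from printed decadal
#' trends. Mann-Kendall (see [mann_kendall()]) supplies trend significance.
#'
#' @param series Tibble with columns `year`, `value`.
#' @param period Length-2 vector `(start_year, end_year)`, inclusive.
#' @return One-row tibble: `slope` (degC/decade), `intercept` (degC at year
#'   0), `start_year`, `end_year`, `total_change` (degC over the period),
#'   `n_years` used.
#' @export
decadal_trend <- function(series, period = c(1961, 2010)) {
  stopifnot_cols(series, c("year", "value"), "series")
  s <- series %>%
    filter(.data$year >= period[1], .data$year <= period[2],
           !is.na(.data$value))
  if (nrow(s) < 10) abort("need at least 10 non-missing years in the period")
  fit <- lm(value ~ year, data = s)
  slope_dec <- unname(coef(fit)[2]) * 10
  tibble(slope = slope_dec, intercept = unname(coef(fit)[1]),
         start_year = period[1], end_year = period[2],
         total_change = slope_dec * (period[2] - period[1]) / 10,
         n_years = nrow(s))
}

#' Resample control-run segments
#'
#' Draws fixed-length segments uniformly (with replacement over admissible
#' start years) from a long unforced control series and records each
#' segment's mean, standard deviation, and decadal trend. This turns a
#' single pre-industrial control run into a null distribution of 50-year
#' climate statistics against which observed trends are judged.
#'
#' @param series Tibble with columns `year`, `value`; length at least
#'   `segment_length`.
#' @param n_segments Number of segments (100 by default).
#' @param segment_length Segment length in years (50 by default).
#' @param seed Integer seed.
#' @return Tibble with one row per segment: `segment`, `start_year`, `mean`,
#'   `sd`, `trend` (degC/decade).
#' @export
resample_control <- function(series, n_segments = 100, segment_length = 50,
                             seed = 1) {
  stopifnot_cols(series, c("year", "value"), "series")
  s <- arrange(series, .data$year)
  n <- nrow(s)
  if (n < segment_length) abort("series shorter than segment_length")
  starts <- with_seed(seed, sample.int(n - segment_length + 1, n_segments,
                                       replace = TRUE))
  purrr::map_dfr(seq_len(n_segments), function(i) {
    seg <- s[starts[i] + seq_len(segment_length) - 1, ]
    tr <- unname(coef(lm(value ~ year, data = seg))[2]) * 10
    tibble(segment = i, start_year = seg$year[1],
           mean = mean(seg$value), sd = stats::sd(seg$value), trend = tr)
  })
}

#' Mann-Kendall trend test
#'
#' Kendall's S statistic of the series against time, with the tie-corrected
#' variance and a continuity-corrected normal approximation for the
#' two-sided p-value; tau is the tie-adjusted (tau-b) correlation. For short
#' series (n <= 8, no ties) the exact permutation p-value is used instead.
#'
#' @param x Numeric series (no missing values), n >= 4.
#' @param exact Use the exact permutation distribution of S; default for
#'   n <= 8 with no ties.
#' @return One-row tibble: `s`, `tau`, `p`, `var_s`, `n`, `method`.
#' @export
mann_kendall <- function(x, exact = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) abort("series must have no missing values")
  n <- length(x)
  if (n < 4) abort("need at least 4 observations")
  sgn <- sign(outer(x, x, function(a, b) b - a))   # sgn[i, j] = sign(x_j - x_i)
  S <- sum(sgn[upper.tri(sgn)])
  ties <- table(x)
  ties <- ties[ties > 1]
  has_ties <- length(ties) > 0
  if (is.null(exact)) exact <- n <= 8 && !has_ties
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - sum(ties * (ties - 1) / 2)) * n0)
  tau <- if (denom > 0) S / denom else 0
  if (var_s == 0) {
    return(tibble(s = S, tau = 0, p = 1, var_s = 0, n = n,
                  method = "degenerate"))
  }
  if (exact) {
    if (has_ties) abort("exact Mann-Kendall p is only available without ties")
    perms <- exact_mk_s_distribution(n)
    p <- mean(abs(perms) >= abs(S))
    method <- "exact"
  } else {
    z <- (S - sign(S)) / sqrt(var_s)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  tibble(s = S, tau = tau, p = p, var_s = var_s, n = n, method = method)
}

# Exact null distribution of Kendall's S over all orderings of n distinct
# values, built by the standard convolution over insertion positions.
exact_mk_s_distribution <- function(n) {
  # number of permutations of 1..n with k inversions, via generating function
  counts <- 1
  for (m in 2:n) {
    counts <- round(stats::convolve(counts, rev(rep(1, m)), type = "open"))
  }
  inv <- seq_along(counts) - 1              # inversions 0 .. n(n-1)/2
  s_vals <- n * (n - 1) / 2 - 2 * inv       # S = C - 2 * inversions
  rep(s_vals, times = counts)
}

#' Pre/post break-year comparison of an annual series
#'
#' Splits an annual series at a break year (the pre window includes the
#' break year itself), reports window means and variances, the Mann-Kendall
#' test over the full series, and a two-sided F test on the variance ratio
#' pre/post.
#'
#' @param series Tibble with columns `year`, `value`.
#' @param break_year Last year of the pre window (default 1976, the winter
#'   before the abrupt 1977 warming).
#' @return One-row tibble: `break_year`, `pre_mean`, `post_mean`, `pre_var`,
#'   `post_var`, `delta_mean`, `mk_tau`, `mk_p`, `f_stat`, `f_p`, `n_pre`,
#'   `n_post`.
#' @export
pre_post_comparison <- function(series, break_year = 1976) {
  stopifnot_cols(series, c("year", "value"), "series")
  s <- series %>% filter(!is.na(.data$value)) %>% arrange(.data$year)
  pre <- s$value[s$year <= break_year]
  post <- s$value[s$year > break_year]
  if (length(pre) < 3 || length(post) < 3) {
    abort("need at least 3 years on each side of the break")
  }
  mk <- mann_kendall(s$value)
  f_stat <- var(pre) / var(post)
  f_p <- 2 * min(pf(f_stat, length(pre) - 1, length(post) - 1),
                 pf(f_stat, length(pre) - 1, length(post) - 1,
                    lower.tail = FALSE))
  f_p <- min(f_p, 1)
  tibble(break_year = break_year,
         pre_mean = mean(pre), post_mean = mean(post),
         pre_var = var(pre), post_var = var(post),
         delta_mean = mean(post) - mean(pre),
         mk_tau = mk$tau, mk_p = mk$p,
         f_stat = f_stat, f_p = f_p,
         n_pre = length(pre), n_post = length(post))
}

#' Grid-wise pre/post change maps
#'
#' Applies [pre_post_comparison()] to the seasonal mean of every grid cell
#' of a monthly gridded temperature table, yielding per-cell layers of mean
#' change, variance change, Mann-Kendall p, and F-test p. Cells with too few
#' years propagate as missing.
#'
#' @param grid Long-format monthly grid tibble: `lat`, `lon`, `year`,
#'   `month`, `value`.
#' @param break_year Passed to [pre_post_comparison()].
#' @param months Season months (default MAM).
#' @param min_coverage Seasonal coverage fraction per [seasonal_mean()].
#' @return Tibble with one row per cell: `lat`, `lon`, `delta_mean`,
#'   `variance_change` (post minus pre), `mk_p`, `f_p`.
#' @export
change_maps <- function(grid, break_year = 1976, months = 3:5,
                        min_coverage = 0.9) {
  stopifnot_cols(grid, c("lat", "lon", "year", "month", "value"), "grid")
  grid %>%
    group_by(.data$lat, .data$lon) %>%
    dplyr::group_modify(function(cell, key) {
      ann <- seasonal_mean(cell, months = months, min_coverage = min_coverage)
      res <- try(pre_post_comparison(ann, break_year), silent = TRUE)
      if (inherits(res, "try-error")) {
        return(tibble(delta_mean = NA_real_, variance_change = NA_real_,
                      mk_p = NA_real_, f_p = NA_real_))
      }
      tibble(delta_mean = res$delta_mean,
             variance_change = res$post_var - res$pre_var,
             mk_p = res$mk_p, f_p = res$f_p)
    }) %>%
    ungroup()
}

#' Station-vs-model comparison table
#'
#' Means, standard deviations, 1961-2010 decadal trends and total change
#' for a set of annual spring-temperature records (stations, gridded cells,
#' model ensemble means), each over its own full period of record and over
#' the common trend period.
#'
#' @param records Named list of annual-series tibbles (`year`, `value`).
#' @param trend_period Period for the trend columns (default 1961-2010).
#' @return Tibble with one row per record: `record`, `start_year`,
#'   `end_year`, `mean`, `sd`, `mean_common`, `sd_common`, `trend`,
#'   `total_change`.
#' @export
comparison_table <- function(records, trend_period = c(1961, 2010)) {
  purrr::imap_dfr(records, function(s, nm) {
    s <- filter(s, !is.na(.data$value))
    common <- filter(s, .data$year >= trend_period[1],
                     .data$year <= trend_period[2])
    tr <- decadal_trend(s, trend_period)
    tibble(record = nm,
           start_year = min(s$year), end_year = max(s$year),
           mean = mean(s$value), sd = stats::sd(s$value),
           mean_common = mean(common$value), sd_common = stats::sd(common$value),
           trend = tr$slope, total_change = tr$total_change)
  })
}
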