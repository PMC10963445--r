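# Seeded generators producing inputs with the statistical structure every
# analysis stage assumes: a mean-shift spring-temperature series, a red-noise
# winter circulation index, ring-width series with age trend and time-varying
# climate coupling, NDVI seasonal curves whose green-up tracks temperature,
# and a loading-pattern monthly grid. Defaults are the study conditions:
# annual spring temperature 1911-2020 with a regime break after 1976
# (pre mean 3.33 degC, variance 1.33; post mean 4.60, variance 3.00) and
# lag-1 autocorrelation 0.2.

# AR(1) noise with unit marginal variance (innovation variance derived).
ar1_noise <- function(n, ar1) {
  if (abs(ar1) >= 1) abort("|ar1| must be < 1")
  innov_sd <- sqrt(1 - ar1^2)
  z <- numeric(n)
  z[1] <- rnorm(1)
  if (n > 1) for (t in 2:n) z[t] <- ar1 * z[t - 1] + innov_sd * rnorm(1)
  z
}

#' Generate a regime-shift spring temperature series
#'
#' AR(1) noise with the stated marginal variance around a piecewise mean
#' (pre/post the break year), plus an optional linear trend. The defaults
#' reproduce the effect size of a northern-Minnesota spring record: mean
#' 3.33 degC (variance 1.33) through 1976, mean 4.60 degC (variance 3.00)
#' after.
#'
#' @param years Calendar years (default 1911:2020).
#' @param break_year Last pre-regime year (default 1976).
#' @param pre_mean,pre_var,post_mean,post_var Regime means (degC) and
#'   variances (degC^2).
#' @param trend Linear trend in degC/decade added across the whole series
#'   (default 0; the mean shift carries the signal).
#' @param ar1 Lag-1 autocorrelation of the noise (default 0.2).
#' @param seed Integer seed.
#' @return Tibble with columns `year`, `value`, plus attribute `truth`
#'   (the generating configuration).
#' @export
gen_spring_temperature <- function(years = 1911:2020, break_year = 1976,
                                   pre_mean = 3.33, pre_var = 1.33,
                                   post_mean = 4.60, post_var = 3.00,
                                   trend = 0, ar1 = 0.2, seed = 1) {
  if (pre_var < 0 || post_var < 0) abort("variances must be non-negative")
  n <- length(years)
  z <- with_seed(child_seed(seed, "spring-temperature"), ar1_noise(n, ar1))
  pre <- years <= break_year
  mu <- ifelse(pre, pre_mean, post_mean)
  sdv <- ifelse(pre, sqrt(pre_var), sqrt(post_var))
  value <- mu + sdv * z + trend * (years - years[1]) / 10
  out <- tibble(year = as.integer(years), value = value)
  attr(out, "truth") <- list(break_year = break_year, pre_mean = pre_mean,
                             pre_var = pre_var, post_mean = post_mean,
                             post_var = post_var, trend = trend, ar1 = ar1,
                             seed = seed)
  out
}

#' Generate a monthly red-noise circulation index
#'
#' Standardised monthly AR(1) index (PNA/NAM-like), optionally with a
#' sustained positive phase offset over a span of years — emulating, e.g.,
#' a prolonged positive circulation phase.
#'
#' @param years Calendar years covered (every month of each).
#' @param ar1 Month-to-month autocorrelation (default 0.5).
#' @param phase_offset Mean offset (index units) applied during
#'   `phase_years`.
#' @param phase_years Years receiving the offset (default none).
#' @param name Index name.
#' @param seed Integer seed.
#' @return Tibble with columns `name`, `year`, `month`, `value`.
#' @export
gen_circulation_index <- function(years = 1950:2020, ar1 = 0.5,
                                  phase_offset = 0, phase_years = integer(),
                                  name = "PNA", seed = 1) {
  n <- 12 * length(years)
  z <- with_seed(child_seed(seed, paste0("index-", name)), ar1_noise(n, ar1))
  out <- tidyr::expand_grid(year = as.integer(years), month = 1:12) %>%
    mutate(name = name,
           value = z + ifelse(.data$year %in% phase_years, phase_offset, 0)) %>%
    select("name", "year", "month", "value")
  out
}

#' Generate ring-width series coupled to a climate series
#'
#' Each tree gets a negative-exponential age curve and a shared lognormal
#' tree signal; each of its (two) cores adds core-level noise. Widths are
#' width(t) = ageCurve(t) * exp(beta(t) z_climate(t) + release(t) + noise),
#' where beta may ramp over time (time-varying climate coupling) and
#' releases are sustained step increases emulating stand-wide disturbance.
#'
#' @param climate Tibble (`year`, `value`); the climate signal is its
#'   standardised value.
#' @param n_trees Number of trees (default 15).
#' @param cores_per_tree Cores per tree (default 2).
#' @param negexp `c(a, b, c)` of the age curve a exp(-b t) + c, in mm.
#' @param beta Either a single coupling coefficient or a length-2 vector
#'   `c(beta_start, beta_end)` ramped linearly across the series.
#' @param release_years Years at which a growth release starts.
#' @param release_size Log-scale size of each release (default 0.4).
#' @param release_length Years a release persists (default 10).
#' @param stand_sd Log-scale sd of a stand-wide year effect shared by every
#'   tree (non-climatic common variance: insect outbreaks, stand dynamics).
#' @param tree_sd,core_sd Log-scale noise standard deviations.
#' @param seed Integer seed.
#' @return Tibble with columns `series_id`, `year`, `width` (mm), plus a
#'   `truth` attribute.
#' @export
gen_ring_series <- function(climate, n_trees = 15, cores_per_tree = 2,
                            negexp = c(2, 0.02, 0.5), beta = 0.4,
                            release_years = integer(), release_size = 0.4,
                            release_length = 10, stand_sd = 0.2,
                            tree_sd = 0.15, core_sd = 0.1, seed = 1) {
  stopifnot_cols(climate, c("year", "value"), "climate")
  yrs <- climate$year
  n <- length(yrs)
  z <- as.numeric(scale(climate$value))
  bvec <- if (length(beta) == 2) seq(beta[1], beta[2], length.out = n)
          else rep(beta, n)
  release <- numeric(n)
  for (ry in release_years) {
    hit <- yrs >= ry & yrs < ry + release_length
    release[hit] <- release[hit] + release_size
  }
  age_curve <- negexp[1] * exp(-negexp[2] * seq_len(n)) + negexp[3]
  with_seed(child_seed(seed, "ring-series"), {
    stand_noise <- rnorm(n, sd = stand_sd)
    purrr::map_dfr(seq_len(n_trees), function(tr) {
      tree_noise <- rnorm(n, sd = tree_sd)
      purrr::map_dfr(seq_len(cores_per_tree), function(co) {
        core_noise <- rnorm(n, sd = core_sd)
        tibble(series_id = sprintf("T%02d%s", tr, LETTERS[co]),
               year = as.integer(yrs),
               width = age_curve *
                 exp(bvec * z + release + stand_noise +
                       tree_noise + core_noise))
      })
    })
  }) -> out
  attr(out, "truth") <- list(beta = beta, negexp = negexp,
                             release_years = release_years, seed = seed)
  out
}

#' Generate an NDVI pixel stack whose green-up tracks temperature
#'
#' Per pixel-year a first-order harmonic seasonal curve whose rising
#' 50%-threshold day is base_day + alpha (temp - mean temp) + pixel noise;
#' observations are sampled every `cadence` days over Julian days 1-212,
#' thinned at random by `missing_fraction`, with additive NDVI noise. A
#' categorical cover raster is generated alongside, with per-class
#' sensitivities when `alpha` is named by class.
#'
#' @param temp Tibble (`year`, `value`): spring temperature driving green-up.
#' @param n_pixels Number of pixels.
#' @param alpha Sensitivity in days/degC: a single value, or a named vector
#'   of per-class values (classes assigned to pixels in equal blocks).
#' @param base_day Mean green-up day of year (default 130).
#' @param a0,amplitude Harmonic mean level and amplitude (NDVI units).
#' @param noise_sd Additive NDVI observation noise sd.
#' @param sos_noise_sd Pixel-year jitter of the green-up day (days).
#' @param missing_fraction Fraction of observations dropped (cloud mask).
#' @param cadence Observation spacing in days (default 8).
#' @param seed Integer seed.
#' @return List with `ndvi` (tibble `pixel_id`, `year`, `day`, `ndvi`),
#'   `cover` (tibble `pixel_id`, `cover_class`), and `truth`.
#' @export
gen_ndvi_stack <- function(temp, n_pixels = 50, alpha = -3, base_day = 130,
                           a0 = 0.5, amplitude = 0.25, noise_sd = 0.02,
                           sos_noise_sd = 2, missing_fraction = 0.1,
                           cadence = 8, seed = 1) {
  stopifnot_cols(temp, c("year", "value"), "temp")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("missing_fraction must be in [0, 1)")
  }
  classes <- if (is.null(names(alpha))) {
    tibble(pixel_id = sprintf("px%04d", seq_len(n_pixels)),
           cover_class = "all", alpha = alpha)
  } else {
    cls <- sort(rep(names(alpha), length.out = n_pixels)) # near-equal blocks
    tibble(pixel_id = sprintf("px%04d", seq_len(n_pixels)),
           cover_class = cls, alpha = alpha[cls])
  }
  tanom <- temp$value - mean(temp$value)
  om <- 2 * pi / 365
  days <- seq(1, 212, by = cadence)
  ndvi <- with_seed(child_seed(seed, "ndvi-stack"), {
    purrr::map_dfr(seq_len(n_pixels), function(px) {
      purrr::map_dfr(seq_along(temp$year), function(iy) {
        sos <- base_day + classes$alpha[px] * tanom[iy] +
          rnorm(1, sd = sos_noise_sd)
        # rising 50% crossing at `sos`: peak sits a quarter period later
        phi <- om * sos + pi / 2
        keep <- runif(length(days)) >= missing_fraction
        tibble(pixel_id = classes$pixel_id[px],
               year = temp$year[iy], day = days[keep],
               ndvi = pmin(1, pmax(-1,
                 a0 + amplitude * cos(om * days[keep] - phi) +
                   rnorm(sum(keep), sd = noise_sd))))
      })
    })
  })
  list(ndvi = ndvi,
       cover = select(classes, "pixel_id", "cover_class"),
       truth = list(alpha = alpha, base_day = base_day, a0 = a0,
                    amplitude = amplitude, seed = seed))
}

#' Generate a monthly temperature grid loaded on a winter index
#'
#' Cell temperature = monthly climatology + loading(cell) x winter-mean
#' index of the year + noise, on a regular 0.5 degree grid. The loading
#' pattern makes some cells teleconnected to the index and others not.
#'
#' @param index Monthly index tibble (`year`, `month`, `value`), as from
#'   [gen_circulation_index()].
#' @param nlat,nlon Grid dimensions.
#' @param lat0,lon0 Southwest cell centre (default 40.25 N, -96.75 E).
#' @param loading Either a function(lat_index, lon_index) returning the
#'   loading, or a matrix `nlat x nlon`; default a west-to-east ramp 0..1.
#' @param climatology Monthly mean temperatures (length 12, degC).
#' @param noise_sd Cell-month noise sd (degC).
#' @param seed Integer seed.
#' @return Long tibble: `lat`, `lon`, `year`, `month`, `value`, with a
#'   `loading` attribute (tibble `lat`, `lon`, `loading`).
#' @export
gen_monthly_grid <- function(index, nlat = 3, nlon = 3, lat0 = 40.25,
                             lon0 = -96.75, loading = NULL,
                             climatology = c(-12, -9, -2, 5, 12, 17,
                                             20, 19, 14, 7, -2, -9),
                             noise_sd = 1, seed = 1) {
  widx <- winter_mean_index(index)
  lats <- lat0 + 0.5 * (seq_len(nlat) - 1)
  lons <- lon0 + 0.5 * (seq_len(nlon) - 1)
  if (is.null(loading)) {
    lmat <- matrix(rep(seq(0, 1, length.out = nlon), each = nlat), nlat, nlon)
  } else if (is.function(loading)) {
    lmat <- outer(seq_len(nlat), seq_len(nlon), Vectorize(loading))
  } else {
    lmat <- matrix(loading, nlat, nlon)
  }
  cells <- tidyr::expand_grid(ilat = seq_len(nlat), ilon = seq_len(nlon))
  yrs <- widx$year[!is.na(widx$value)]
  grid <- with_seed(child_seed(seed, "monthly-grid"), {
    purrr::pmap_dfr(cells, function(ilat, ilon) {
      tidyr::expand_grid(year = yrs, month = 1:12) %>%
        mutate(lat = lats[ilat], lon = lons[ilon],
               value = climatology[.data$month] +
                 lmat[ilat, ilon] *
                 widx$value[match(.data$year, widx$year)] +
                 rnorm(dplyr::n(), sd = noise_sd)) %>%
        select("lat", "lon", "year", "month", "value")
    })
  })
  attr(grid, "loading") <- tibble(
    lat = lats[cells$ilat], lon = lons[cells$ilon],
    loading = lmat[as.matrix(cells)])
  grid
}
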