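test_that("decadal trend recovers exact lines and the total-change convention", {
  s <- tibble::tibble(year = 1961:2010, value = 0.05 * (1961:2010 - 1961))
  tr <- decadal_trend(s, c(1961, 2010))
  expect_equal(tr$slope, 0.5)
  expect_equal(tr$total_change, 0.5 * 4.9)
  # printed decadal trends translate to printed total warming at 4.9 decades
  mk_series <- function(slope_dec) {
    tibble::tibble(year = 1961:2010,
                   value = slope_dec / 10 * (1961:2010 - 1961))
  }
  expect_equal(round(decadal_trend(mk_series(0.334))$total_change, 2), 1.64)
  expect_equal(round(decadal_trend(mk_series(0.414))$total_change, 2), 2.03)
  expect_equal(round(decadal_trend(mk_series(0.339))$total_change, 2), 1.66)
  expect_error(decadal_trend(s[1:5, ], c(1961, 1966)), "at least 10")
})

test_that("total change always equals slope times span over ten", {
  set.seed(5)
  for (i in 1:10) {
    s <- tibble::tibble(year = 1950:2014, value = rnorm(65))
    tr <- decadal_trend(s, c(1961, 2010))
    expect_equal(tr$total_change, tr$slope * (2010 - 1961) / 10)
  }
})

test_that("control-run resampling has the stated structure and determinism", {
  const <- tibble::tibble(year = 1850:2550, value = 3.5)
  rs <- resample_control(const, n_segments = 20, seed = 4)
  expect_equal(nrow(rs), 20)
  expect_true(all(rs$mean == 3.5))
  expect_true(all(abs(rs$trend) < 1e-12))
  # segments sit wholly inside the source series
  expect_true(all(rs$start_year >= 1850 & rs$start_year + 49 <= 2550))
  set.seed(99)
  noise <- tibble::tibble(year = 1850:2550, value = rnorm(701))
  a <- resample_control(noise, seed = 11)
  b <- resample_control(noise, seed = 11)
  expect_identical(a, b)
  # iid input: segment trends are centred on zero
  expect_lt(abs(mean(a$trend)), 3 * sd(a$trend) / sqrt(nrow(a)))
  expect_error(resample_control(noise[1:30, ]), "shorter")
})

test_that("Mann-Kendall matches exhaustive enumeration and handles degeneracy", {
  x <- c(3, 1, 4, 2, 5)
  oracle <- oracle_mk(x)
  got <- mann_kendall(x)
  expect_equal(got$s, oracle$S)
  expect_equal(got$p, oracle$p)
  expect_equal(got$method, "exact")
  expect_equal(mann_kendall(1:15)$tau, 1)
  alleq <- mann_kendall(rep(2, 10))
  expect_equal(alleq$tau, 0)
  expect_equal(alleq$p, 1)
  expect_error(mann_kendall(c(1, 2, 3)), "at least 4")
})

test_that("Mann-Kendall agrees with the independent Kendall correlation route", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(40)
    got <- mann_kendall(x)
    ct <- suppressWarnings(cor.test(seq_along(x), x, method = "kendall"))
    expect_equal(got$tau, unname(ct$estimate), tolerance = 1e-12)
    # continuity-corrected normal vs cor.test's exact/asymptotic p: close
    expect_equal(got$p, ct$p.value, tolerance = 0.02)
  }
})

test_that("pre/post comparison reports window statistics and a symmetric F test", {
  s <- tibble::tibble(year = 1974:1979, value = c(1, 2, 3, 11, 12, 13))
  pp <- pre_post_comparison(s, break_year = 1976)
  expect_equal(pp$pre_mean, 2)
  expect_equal(pp$post_mean, 12)
  expect_equal(pp$pre_var, 1)
  expect_equal(pp$post_var, 1)
  expect_equal(pp$f_stat, 1)
  expect_equal(pp$delta_mean, 10)
  # identical windows: F = 1, delta mean = 0
  s2 <- tibble::tibble(year = 1971:1982, value = rep(c(1, 5, 3, 2, 4, 6), 2))
  pp2 <- pre_post_comparison(s2, break_year = 1976)
  expect_equal(pp2$f_stat, 1)
  expect_equal(pp2$delta_mean, 0)
  # swapping windows inverts F and leaves the two-sided p unchanged
  set.seed(3)
  s3 <- tibble::tibble(year = 1960:1999, value = rnorm(40, sd = rep(c(1, 2), each = 20)))
  a <- pre_post_comparison(s3, break_year = 1979)
  flipped <- tibble::tibble(year = 1960:1999,
                            value = c(s3$value[21:40], s3$value[1:20]))
  b <- pre_post_comparison(flipped, break_year = 1979)
  expect_equal(a$f_stat, 1 / b$f_stat)
  expect_equal(a$f_p, b$f_p)
  expect_error(pre_post_comparison(s, break_year = 1975), "at least 3")
})

test_that("pre/post comparison recovers the generating regime parameters", {
  reps <- t(sapply(1:10, function(i) {
    pp <- pre_post_comparison(gen_spring_temperature(seed = 600 + i))
    c(pp$pre_mean, pp$post_mean)
  }))
  # MC standard errors: sd/sqrt(n_years x reps)
  expect_equal(mean(reps[, 1]), 3.33,
               tolerance = 3 * sqrt(1.33 / (66 * 10)) + 0.02)
  expect_equal(mean(reps[, 2]), 4.60,
               tolerance = 3 * sqrt(3.00 / (44 * 10)) + 0.02)
})

test_that("change maps equal scalar calls cell by cell", {
  idx <- gen_circulation_index(years = 1949:2010, seed = 5)
  grid <- gen_monthly_grid(idx, nlat = 2, nlon = 2, seed = 6)
  # impose a known shift on one cell
  grid <- grid %>%
    dplyr::mutate(value = value +
                    ifelse(lat == 40.25 & lon == -96.75 & year > 1976, 3, 0))
  cm <- change_maps(grid, break_year = 1976)
  expect_equal(nrow(cm), 4)
  for (i in seq_len(nrow(cm))) {
    cell <- grid %>%
      dplyr::filter(lat == cm$lat[i], lon == cm$lon[i])
    pp <- pre_post_comparison(seasonal_mean(cell, months = 3:5), 1976)
    expect_equal(cm$delta_mean[i], pp$delta_mean)
    expect_equal(cm$mk_p[i], pp$mk_p)
    expect_equal(cm$f_p[i], pp$f_p)
  }
  # the shifted cell shows the imposed mean change
  shifted <- cm %>% dplyr::filter(lat == 40.25, lon == -96.75)
  rest <- cm %>% dplyr::filter(!(lat == 40.25 & lon == -96.75))
  expect_gt(shifted$delta_mean, max(rest$delta_mean) + 1)
})

test_that("uniformly shifted grids give a uniform delta_mean", {
  yrs <- 1950:2010
  cells <- tidyr::expand_grid(lat = c(45.25, 45.75), lon = c(-90.25, -89.75))
  grid <- tidyr::expand_grid(cells, year = yrs, month = 1:12) %>%
    dplyr::mutate(value = 5 + ifelse(year > 1976, 1.5, 0))
  cm <- change_maps(grid, break_year = 1976)
  expect_equal(cm$delta_mean, rep(1.5, 4))
  expect_equal(cm$variance_change, rep(0, 4), tolerance = 1e-12)
})

test_that("the comparison table reports per-record and common-window statistics", {
  recs <- list(
    warm = tibble::tibble(year = 1911:2020,
                          value = 3 + 0.02 * (1911:2020 - 1911)),
    flat = tibble::tibble(year = 1901:2020, value = rep(4, 120)))
  tab <- comparison_table(recs)
  expect_equal(tab$record, c("warm", "flat"))
  expect_equal(tab$trend[2], 0)
  expect_equal(tab$total_change[1], 0.2 * 4.9, tolerance = 1e-10)
  expect_equal(tab$mean_common[2], 4)
})
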