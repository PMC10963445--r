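harmonic_curve <- function(a0, a1, b1, day) {
  a0 + a1 * cos(2 * pi * day / 365) + b1 * sin(2 * pi * day / 365)
}

test_that("harmonic fitting is exact on noiseless data and flags bad sampling", {
  days <- seq(5, 210, by = 7)
  ts <- tibble::tibble(day = days, ndvi = harmonic_curve(0.5, -0.25, 0, days))
  fit <- fit_harmonic(ts)
  expect_equal(fit$a0, 0.5, tolerance = 1e-10)
  expect_equal(fit$a1, -0.25, tolerance = 1e-10)
  expect_equal(fit$b1, 0, tolerance = 1e-10)
  expect_equal(fit$fitted_min, 0.25, tolerance = 1e-10)
  expect_equal(fit$fitted_max, 0.75, tolerance = 1e-10)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  const <- tibble::tibble(day = days, ndvi = 0.4)
  cf <- fit_harmonic(const)
  expect_equal(cf$amplitude, 0, tolerance = 1e-12)
  expect_equal(cf$fitted_min, 0.4, tolerance = 1e-10)
  expect_error(fit_harmonic(ts[1:5, ]), "at least 8")
  expect_error(fit_harmonic(tibble::tibble(day = 1:10, ndvi = 0.1)),
               "span")
  expect_error(fit_harmonic(tibble::tibble(day = c(1:7, 300),
                                           ndvi = 0.1)), "1..212")
})

test_that("noisy harmonic coefficients are recovered within sampling error", {
  set.seed(9)
  days <- seq(1, 212, by = 4)
  ests <- t(sapply(1:30, function(i) {
    ts <- tibble::tibble(day = days,
                         ndvi = harmonic_curve(0.45, -0.2, 0.1, days) +
                           rnorm(length(days), sd = 0.03))
    unlist(fit_harmonic(ts)[c("a0", "a1", "b1")])
  }))
  for (j in 1:3) {
    truth <- c(0.45, -0.2, 0.1)[j]
    expect_lt(abs(mean(ests[, j]) - truth), 3 * sd(ests[, j]) / sqrt(30))
  }
})

test_that("the NDVI50 date is the rising mid-amplitude crossing", {
  days <- seq(1, 212, by = 4)
  ts <- tibble::tibble(day = days, ndvi = harmonic_curve(0.5, -0.25, 0, days))
  fit <- fit_harmonic(ts)
  dt <- ndvi50_date(fit)
  expect_equal(dt$ndvi50, 0.5, tolerance = 1e-9)
  expect_equal(dt$sos_day, 91.25, tolerance = 1e-6)
  expect_equal(dt$flag, "ok")
  # defining property: curve value at sos equals the threshold, rising
  expect_equal(harmonic_curve(fit$a0, fit$a1, fit$b1, dt$sos_day),
               dt$ndvi50, tolerance = 1e-9)
  flat <- ndvi50_date(fit_harmonic(tibble::tibble(day = days, ndvi = 0.3)))
  expect_equal(flat$flag, "flat")
  expect_true(is.na(flat$sos_day))
})

test_that("closed-form crossing equals numeric root finding on random fits", {
  set.seed(77)
  n_checked <- 0
  for (i in 1:100) {
    a0 <- runif(1, 0.2, 0.6)
    ang <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.05, 0.3)
    fit <- tibble::tibble(a0 = a0, a1 = amp * cos(ang), b1 = amp * sin(ang),
                          amplitude = amp, phase = ang,
                          fitted_min = a0 - amp, fitted_max = a0 + amp)
    dt <- ndvi50_date(fit)
    if (dt$flag != "ok") next
    n_checked <- n_checked + 1
    g <- function(t) harmonic_curve(a0, fit$a1, fit$b1, t) - dt$ndvi50
    # bracket a rising root around the closed-form crossing
    root <- uniroot(g, c(dt$sos_day - 80, dt$sos_day + 80), tol = 1e-9)$root
    expect_equal(dt$sos_day, root, tolerance = 1e-6)
    expect_gt(g(dt$sos_day + 1e-3), 0)   # rising
    expect_lt(g(dt$sos_day - 1e-3), 0)
  }
  expect_gt(n_checked, 50)
})

test_that("green-up shifts are recovered equivariantly from synthetic stacks", {
  temp <- tibble::tibble(year = 2003:2021, value = rep(5, 19))
  for (d in c(0, 10)) {
    stack <- gen_ndvi_stack(temp, n_pixels = 1, base_day = 120 + d,
                            sos_noise_sd = 0, noise_sd = 0,
                            missing_fraction = 0, seed = 3)
    dates <- phenology_dates(stack$ndvi)
    expect_true(all(dates$flag == "ok"))
    expect_equal(mean(dates$sos_day), 120 + d, tolerance = 0.5)
  }
})

test_that("pixel sensitivity recovers exact and hand-computed relationships", {
  temp <- tibble::tibble(year = 2003:2012, value = c(2, 4, 3, 5, 6, 4, 7, 5, 8, 6))
  dates <- tibble::tibble(year = temp$year, sos_day = 120 - 3 * temp$value)
  ps <- pixel_sensitivity(dates, temp)
  expect_equal(ps$alpha, -3)
  expect_equal(ps$r, -1)
  # hand-computed six-point pair
  sos6 <- c(130, 124, 128, 121, 119, 125)
  t6 <- c(2.0, 4.5, 3.1, 5.2, 6.0, 3.8)
  ps6 <- pixel_sensitivity(tibble::tibble(year = 2001:2006, sos_day = sos6),
                           tibble::tibble(year = 2001:2006, value = t6))
  expect_equal(ps6$r, cor(sos6, t6))
  expect_equal(ps6$alpha, unname(coef(lm(sos6 ~ t6))[2]))
  const <- pixel_sensitivity(dates, dplyr::mutate(temp, value = 5))
  expect_equal(const$flag, "constant temperature")
  short <- pixel_sensitivity(dates[1:3, ], temp)
  expect_equal(short$flag, "insufficient overlap")
})

test_that("sensitivity alpha is recovered across a noisy synthetic stack", {
  temp <- gen_spring_temperature(years = 2003:2021, break_year = 1900,
                                 pre_mean = 5, pre_var = 1, post_mean = 5,
                                 post_var = 1, seed = 12)
  stack <- gen_ndvi_stack(temp, n_pixels = 40, alpha = -3, seed = 13)
  sens <- sensitivity_map(phenology_dates(stack$ndvi), temp)
  ok <- sens[sens$flag == "ok", ]
  expect_gt(nrow(ok), 35)
  expect_lt(abs(mean(ok$alpha) - (-3)), 3 * sd(ok$alpha) / sqrt(nrow(ok)))
  expect_lt(mean(ok$r > 0), 0.1)  # warming pulls green-up earlier
})

test_that("class summaries aggregate correctly and conserve pixel counts", {
  temp <- gen_spring_temperature(years = 2003:2021, break_year = 1900,
                                 pre_mean = 5, pre_var = 1.5, post_mean = 5,
                                 post_var = 1.5, seed = 21)
  stack <- gen_ndvi_stack(temp, n_pixels = 40,
                          alpha = c(conifer = -4, broadleaf = -1), seed = 22)
  sens <- sensitivity_map(phenology_dates(stack$ndvi), temp)
  cls <- classify_and_summarize(sens, stack$cover)
  expect_equal(sum(cls$by_class$n) + cls$n_unclassified +
                 sum(is.na(sens$r)), nrow(sens))
  expect_lt(cls$by_class$alpha_mean[cls$by_class$cover_class == "conifer"],
            cls$by_class$alpha_mean[cls$by_class$cover_class == "broadleaf"])
  # single-class raster reproduces whole-map statistics
  one <- classify_and_summarize(sens, dplyr::mutate(stack$cover,
                                                    cover_class = "all"))
  ok <- sens[!is.na(sens$r), ]
  expect_equal(one$by_class$r_mean, mean(ok$r))
  expect_equal(one$by_class$n, nrow(ok))
  # unknown pixels are excluded and counted
  cover_half <- stack$cover[1:20, ]
  half <- classify_and_summarize(sens, cover_half)
  expect_equal(half$n_unclassified, 20)
})
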