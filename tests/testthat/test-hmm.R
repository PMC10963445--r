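test_that("one-state forward likelihood is the sum of Gaussian log densities", {
  x <- c(0.4, -1.2, 2.1, 0.3)
  p <- hmm_params(1, matrix(1, 1, 1), means = 0.5, sds = 1.3)
  expect_equal(log_forward(x, p), sum(dnorm(x, 0.5, 1.3, log = TRUE)))
})

test_that("forward, posteriors and Viterbi agree with exhaustive enumeration", {
  set.seed(101)
  for (i in 1:12) {
    inst <- random_hmm_instance()
    p <- hmm_params(inst$init, inst$trans_base, inst$means, inst$sds)
    oracle <- oracle_hmm(inst$x, inst$init, inst$trans_base, inst$means,
                         inst$sds)
    expect_equal(log_forward(inst$x, p), oracle$loglik, tolerance = 1e-10)
    dec <- posterior_decode(inst$x, p)
    expect_lt(max(abs(dec$posteriors - oracle$gamma)), 1e-8)
    expect_equal(rowSums(dec$posteriors), rep(1, inst$T_), tolerance = 1e-10)
  }
})

test_that("covariate models with zero coefficients reduce to the homogeneous model", {
  set.seed(7)
  x <- rnorm(10)
  Z <- matrix(rnorm(20), 10, 2)
  tb <- matrix(c(0.85, 0.15, 0.25, 0.75), 2, byrow = TRUE)
  p0 <- hmm_params(c(0.9, 0.1), tb, c(-1, 1), c(1, 0.8))
  pz <- hmm_params(c(0.9, 0.1), tb, c(-1, 1), c(1, 0.8),
                   coefs = array(0, dim = c(2, 2, 2)))
  expect_identical(log_forward(x, pz, covariates = Z), log_forward(x, p0))
  expect_identical(posterior_decode(x, pz, covariates = Z)$posteriors,
                   posterior_decode(x, p0)$posteriors)
})

test_that("covariate transitions match the oracle's logit parameterisation", {
  set.seed(12)
  inst <- random_hmm_instance(T_max = 6, K_max = 2)
  K <- inst$K
  coefs <- array(rnorm(K * K * 2, sd = 0.5), dim = c(K, K, 2))
  for (i in seq_len(K)) coefs[i, i, ] <- 0
  Z <- matrix(rnorm(inst$T_ * 2), inst$T_, 2)
  p <- hmm_params(inst$init, inst$trans_base, inst$means, inst$sds, coefs)
  oracle <- oracle_hmm(inst$x, inst$init, inst$trans_base, inst$means,
                       inst$sds, coefs, Z)
  expect_equal(log_forward(inst$x, p, covariates = Z), oracle$loglik,
               tolerance = 1e-10)
  dec <- posterior_decode(inst$x, p, covariates = Z)
  expect_lt(max(abs(dec$posteriors - oracle$gamma)), 1e-8)
})

test_that("malformed inputs are rejected", {
  p <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), c(0, 1), c(1, 1),
                  coefs = array(0.1, dim = c(2, 2, 1)))
  expect_error(log_forward(rnorm(5), p, covariates = matrix(0, 4, 1)),
               "covariates have")
  expect_error(log_forward(c(1, NA, 2), p), "gaps")
  expect_error(hmm_params(1, matrix(1, 1, 1), 0, 0), "positive")
  expect_error(hmm_params(c(0.6, 0.6), matrix(0.5, 2, 2), c(0, 1), c(1, 1)),
               "sum to 1")
})

test_that("one-state EM is the closed-form Gaussian fit", {
  x <- tibble::tibble(year = 1961:2000, value = rnorm(40, 3, 2))
  f <- fit_em(x, 1)
  expect_equal(f$params$means, mean(x$value))
  expect_equal(f$params$sds, sqrt(mean((x$value - mean(x$value))^2)))
  expect_equal(f$loglik,
               sum(dnorm(x$value, f$params$means, f$params$sds, log = TRUE)))
  expect_equal(f$n_free_params, 2L)
  expect_true(all(f$posteriors == 1))
})

test_that("EM decodes a well-separated two-state path exactly", {
  set.seed(33)
  true_path <- rep(c(1, 2), times = c(30, 25))
  x <- rnorm(55, mean = c(0, 10)[true_path], sd = 1)
  f <- fit_em(tibble::tibble(year = 1946:2000, value = x), 2, seed = 5)
  expect_equal(f$map_path, true_path)
  expect_equal(f$transition_year, 1975)
  expect_equal(f$params$means, c(0, 10), tolerance = 0.5)
})

test_that("EM log-likelihood is monotone and states are ordered by mean", {
  for (s in 1:4) {
    obs <- gen_spring_temperature(seed = 200 + s)
    f <- fit_em(obs, 2, seed = s, n_restarts = 2)
    expect_true(all(diff(f$loglik_trace) > -1e-8))
    expect_true(f$params$means[1] < f$params$means[2])
    expect_equal(rowSums(f$posteriors), rep(1, nrow(obs)), tolerance = 1e-10)
  }
})

test_that("EM recovers the regime means of the default generator", {
  # pre-shift N(3.33, 1.33), post-shift N(4.60, 3.00): average fitted state
  # means over replicates sit near the generator truth
  ms <- t(sapply(1:12, function(i) {
    fit_em(gen_spring_temperature(seed = 400 + i), 2, seed = i,
           n_restarts = 2)$params$means
  }))
  expect_equal(mean(ms[, 1]), 3.33, tolerance = 0.45)
  expect_equal(mean(ms[, 2]), 4.60, tolerance = 0.65)
})

test_that("transition years summarise single-switch paths only", {
  expect_equal(identify_transition_year(c(1, 1, 1, 2, 2), 1974:1978), 1976L)
  expect_true(is.na(identify_transition_year(c(1, 2, 1, 2), 1974:1977)))
  expect_true(is.na(identify_transition_year(rep(1, 5), 1974:1978)))
  expect_error(identify_transition_year(c(1, 2), 1974:1976), "align")
})

test_that("information criteria reproduce the printed model-selection arithmetic", {
  # two-state covariate-free Gaussian HMM: k = 7
  expect_equal(hmm_n_free_params(2, 0), 7L)
  expect_equal(information_criteria(68.29, 7, 114)$aic, -122.58)
  # one-state model: k = 2; printed -90.73 reflects rounding of the
  # unrounded log-likelihood
  expect_equal(hmm_n_free_params(1, 0), 2L)
  expect_equal(information_criteria(47.36, 2, 114)$aic, -90.73,
               tolerance = 0.02)
  # bic - aic = k (ln T - 2) for any fit
  ic <- information_criteria(-12.3, 5, 61)
  expect_equal(ic$bic - ic$aic, 5 * (log(61) - 2))
})

test_that("model comparison reports differences, LRT and significance codes", {
  obs <- gen_spring_temperature(seed = 77)
  f1 <- fit_em(obs, 1)
  f2 <- fit_em(obs, 2, seed = 3, n_restarts = 2)
  same <- compare_models(f1, f1)
  expect_equal(same$delta_aic, 0)
  expect_equal(same$lrt_stat, 0)
  expect_equal(same$lrt_p, 1)
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$delta_aic, f2$aic - f1$aic)
  expect_equal(cmp$lrt_stat, 2 * (f2$loglik - f1$loglik))
  expect_equal(cmp$lrt_df, 5L)
  expect_equal(cmp$lrt_p, pchisq(cmp$lrt_stat, 5, lower.tail = FALSE))
  # printed AIC difference: -122.58 - (-90.73)
  expect_equal(-122.58 - (-90.73), -31.85)
  f_short <- fit_em(obs[1:60, ], 1)
  expect_error(compare_models(f_short, f2), "identical observation")
})

test_that("the model suite selects one state for constant data and two for a shift", {
  const <- tibble::tibble(year = 1961:2010, value = rep(2.5, 50))
  s1 <- fit_model_suite(const)
  expect_lt(s1$aic[s1$model == "1-state"], s1$aic[s1$model == "2-state"])
  shift <- tibble::tibble(year = 1931:2010,
                          value = rep(c(0, 6), each = 40) +
                            rnorm(80, sd = 0.5))
  s2 <- fit_model_suite(shift, seed = 9)
  expect_lt(s2$aic[s2$model == "2-state"], s2$aic[s2$model == "1-state"])
  expect_equal(s2$transition_year[s2$model == "2-state"], 1970L)
})

test_that("adding the generating covariate never lowers the likelihood", {
  obs <- gen_spring_temperature(seed = 55)
  covs <- tibble::tibble(year = obs$year,
                         driver = as.numeric(obs$year > 1976) + rnorm(110, sd = 0.1))
  suite <- fit_model_suite(obs, covariates = covs, seed = 2, n_restarts = 2)
  l_plain <- suite$loglik[suite$model == "2-state (covariate window)"]
  l_cov <- suite$loglik[suite$model == "2-state + covariates"]
  expect_gte(l_cov, l_plain - 1e-6)
})

test_that("hmm_fit tidiers expose parameters, diagnostics and posteriors", {
  obs <- gen_spring_temperature(seed = 17)
  f <- fit_em(obs, 2, seed = 1, n_restarts = 2)
  td <- generics::tidy(f)
  expect_equal(td$state, 1:2)
  expect_equal(td$mean, f$params$means)
  gl <- generics::glance(f)
  expect_equal(gl$aic, 2 * gl$n_free_params - 2 * gl$loglik)
  expect_equal(gl$bic, gl$n_free_params * log(gl$n_obs) - 2 * gl$loglik)
  au <- generics::augment(f)
  expect_equal(nrow(au), nrow(obs))
  expect_equal(au$p_state1 + au$p_state2, rep(1, nrow(obs)), tolerance = 1e-9)
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
})
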