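# springshift

Detection and attribution of abrupt regime shifts in spring climate, and of
their imprint on forest ecosystems. The package grew out of a
northern-Minnesota case study — spring (March–April–May) temperatures that
stepped to a warmer, more variable state after 1976/77, with downstream
consequences for tree growth and canopy phenology — but every component is
generic: it takes ordinary tibbles of annual, monthly, daily, ring-width, or
NDVI records and returns tibbles, so the whole analysis chains with the pipe.

## What it computes

**Regime detection.** Spring-mean temperature series are modelled with a
K-state Gaussian hidden Markov model: observations X_t are emitted from a
hidden climate state S_t as

    X_t | S_t = k  ~  N(mu_k, sigma_k^2),

with a row-stochastic transition matrix P(S_t = j | S_{t-1} = i). Transition
probabilities may depend on covariates (a modelled warming curve, a winter
circulation index) through a row-wise multinomial logit with the row's own
state as reference, so the covariate-free model is recovered exactly at zero
coefficients. Models are fitted by EM (`fit_em()`), decoded by
forward–backward and Viterbi (`posterior_decode()`), and compared by AIC,
BIC, and likelihood-ratio tests (`compare_models()`, `fit_model_suite()`).
A path that switches state exactly once yields a *transition year*.

**Attribution.** `decadal_trend()` (OLS slope, °C/decade, with total change
over a fixed period), `resample_control()` (distributions of 50-year means,
sds and trends from a long unforced control run), `pre_post_comparison()`
(pre/post-break means, variances, Mann–Kendall trend test, two-sided F
test), and `change_maps()` (the same, per grid cell).

**Teleconnections.** `winter_mean_index()` (DJFM means labelled by January's
year) and `correlation_map()` (cell-wise Spearman correlation of gridded
spring temperature with a winter circulation index, with a significance
mask).

**Dendrochronology.** Tucson/RWL I/O (`read_rwl()`, `write_rwl()`),
negative-exponential and 100-year-spline detrending, chronology building
with RBAR and EPS = n·rbar/(n·rbar + 1 − rbar), 10-year running
climate–growth correlations, and block-bootstrap null thresholds with a
Mann–Kendall test for strengthening coupling
(`block_bootstrap_significance()`).

**Phenology.** First-order harmonic fits to NDVI over Julian days 1–212
(`fit_harmonic()`), green-up dated at the 50% threshold
NDVI50 = NDVImin + 0.5·(NDVImax − NDVImin) (`ndvi50_date()`), per-pixel
temperature sensitivity α in days/°C (`sensitivity_map()`), summarised by
forest cover class (`classify_and_summarize()`).

**Synthetic data.** Seeded generators (`gen_spring_temperature()`,
`gen_circulation_index()`, `gen_ring_series()`, `gen_ndvi_stack()`,
`gen_monthly_grid()`) emulate every input with configurable effect sizes, so
the full pipeline (`run_all()`) runs and is tested entirely offline.

## Worked example

Simulate a 1911–2020 spring-temperature record with the study's effect size
(pre-1977 mean 3.33 °C, variance 1.33; after, 4.60 °C and 3.00), then ask
whether a two-state model beats a one-state model:

```r
library(springshift)

obs   <- gen_spring_temperature(seed = 2)
suite <- fit_model_suite(obs, seed = 2, n_restarts = 3)
dplyr::select(suite, -fit)
#> # A tibble: 2 × 11
#>   model   n_states n_covariates n_years loglik   aic   bic delta_aic    lrt_p
#>   <chr>      <int>        <int>   <int>  <dbl> <dbl> <dbl>     <dbl>    <dbl>
#> 1 1-state        1            0     110  -204.  412.  417.     NA    NA
#> 2 2-state        2            0     110  -196.  406.  425.     -5.82  0.00736
#>   significance transition_year
#>   <chr>                  <int>
#> 1 ""                        NA
#> 2 "**"                    1975
```

The two-state model is preferred (ΔAIC = −5.8, LRT p < 0.01) and its decoded
path switches exactly once, in 1975 — one year off this replicate's
generating break after 1976. The fitted states recover the generating
regimes:

```r
generics::tidy(suite$fit[[2]])
#> # A tibble: 2 × 5
#>   state  mean    sd init_prob self_trans
#>   <int> <dbl> <dbl>     <dbl>      <dbl>
#> 1     1  3.25  1.19 1   e+  0      0.985
#> 2     2  4.21  1.85 7.76e-132      1.000
```

Classical pre/post statistics on the same series tell the same story —
a ~1 °C jump in the mean, roughly doubled variance:

```r
pp <- pre_post_comparison(obs)
round(dplyr::select(pp, pre_mean, pre_var, post_mean, post_var,
                    mk_p, f_stat, f_p), 3)
#> # A tibble: 1 × 7
#>   pre_mean pre_var post_mean post_var  mk_p f_stat   f_p
#>      <dbl>   <dbl>     <dbl>    <dbl> <dbl>  <dbl> <dbl>
#> 1     3.21    1.42      4.20     3.34  0.03  0.423 0.002

tr <- decadal_trend(obs, c(1961, 2010))
sprintf("trend %.3f degC/decade, total %.2f degC", tr$slope, tr$total_change)
#> [1] "trend 0.444 degC/decade, total 2.18 degC"
```

`autoplot()` methods visualise fitted HMMs and running-correlation tests;
`run_all(pipeline_config())` executes the five analysis stages end to end on
simulated inputs and writes CSV report tables.

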