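#' Tidy a fitted HMM
#'
#' One row per hidden state: emission mean and sd, initial probability, and
#' the self-transition probability at covariate value zero.
#'
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `state`, `mean`, `sd`, `init_prob`,
#'   `self_trans`.
#' @method tidy hmm_fit
#' @export
tidy.hmm_fit <- function(x, ...) {
  p <- x$params
  tibble(state = seq_len(p$n_states),
         mean = p$means, sd = p$sds,
         init_prob = p$init_probs,
         self_trans = diag(p$trans_base))
}

#' Glance at a fitted HMM
#'
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_states`, `n_covariates`, `n_obs`, `loglik`,
#'   `n_free_params`, `aic`, `bic`, `converged`, `n_iter`,
#'   `transition_year`.
#' @method glance hmm_fit
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble(n_states = x$params$n_states,
         n_covariates = n_covariates(x$params),
         n_obs = length(x$obs),
         loglik = x$loglik, n_free_params = x$n_free_params,
         aic = x$aic, bic = x$bic,
         converged = x$converged, n_iter = x$n_iter,
         transition_year = x$transition_year)
}

#' Augment observations with HMM posteriors
#'
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @return Tibble with `year`, `value`, `map_state`, and one
#'   `p_state<k>` column per state.
#' @method augment hmm_fit
#' @export
augment.hmm_fit <- function(x, ...) {
  out <- tibble(year = x$years, value = x$obs,
                map_state = x$map_path)
  for (k in seq_len(x$params$n_states)) {
    out[[paste0("p_state", k)]] <- x$posteriors[, k]
  }
  out
}

#' @method tidy chronology
#' @export
tidy.chronology <- function(x, ...) {
  tibble(year = x$year, index = x$index, sample_depth = x$sample_depth)
}

#' @method glance chronology
#' @export
glance.chronology <- function(x, ...) {
  tibble(n_series = attr(x, "n_series"), rbar = attr(x, "rbar"),
         eps = attr(x, "eps"), eps_ok = attr(x, "eps_ok"),
         first_year = min(x$year), last_year = max(x$year))
}

#' @method tidy running_cor_test
#' @export
tidy.running_cor_test <- function(x, ...) x$windows

#' @method glance running_cor_test
#' @export
glance.running_cor_test <- function(x, ...) {
  tibble(n_windows = nrow(x$windows), null_threshold = x$null_threshold,
         n_exceed = sum(x$windows$exceeds), mk_tau = x$mk_tau,
         mk_p = x$mk_p, slope = x$slope,
         slope_lo = x$slope_ci[1], slope_hi = x$slope_ci[2],
         n_iter = x$n_iter, block = x$block, level = x$level)
}
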