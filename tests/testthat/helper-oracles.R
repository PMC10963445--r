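# Independent oracles used to cross-check the package's algorithms.
# These deliberately re-derive everything from first principles (exhaustive
# enumeration, hand formulas) and share no code with the implementation.

# Transition matrix at covariate row z under the row-reference multinomial
# logit parameterisation (independent re-derivation).
oracle_trans_at <- function(trans_base, coefs, z) {
  K <- nrow(trans_base)
  eta <- log(trans_base) - matrix(log(diag(trans_base)), K, K)
  if (!is.null(coefs) && length(z) > 0) {
    for (l in seq_along(z)) eta <- eta + coefs[, , l] * z[[l]]
  }
  t(apply(eta, 1, function(r) exp(r) / sum(exp(r))))
}

# Exhaustive-path likelihood and posteriors of a Gaussian HMM.
oracle_hmm <- function(x, init, trans_base, means, sds,
                       coefs = NULL, Z = NULL) {
  T_ <- length(x)
  K <- length(means)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  probs <- apply(paths, 1, function(s) {
    pr <- init[s[1]] * stats::dnorm(x[1], means[s[1]], sds[s[1]])
    if (T_ > 1) {
      for (t in 2:T_) {
        P <- oracle_trans_at(trans_base, coefs,
                             if (is.null(Z)) NULL else Z[t, ])
        pr <- pr * P[s[t - 1], s[t]] *
          stats::dnorm(x[t], means[s[t]], sds[s[t]])
      }
    }
    pr
  })
  total <- sum(probs)
  gamma <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    for (k in seq_len(K)) {
      gamma[t, k] <- sum(probs[paths[, t] == k]) / total
    }
  }
  list(loglik = log(total), gamma = gamma)
}

# Kendall S and exact two-sided permutation p by full enumeration.
oracle_mk <- function(x) {
  n <- length(x)
  kendall_s <- function(v) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + sign(v[j] - v[i])
    s
  }
  S_obs <- kendall_s(x)
  perms <- permutations_of(seq_len(n))
  S_all <- apply(perms, 1, function(idx) kendall_s(x[idx]))
  list(S = S_obs, p = mean(abs(S_all) >= abs(S_obs)))
}

# Exact two-sided permutation p for Spearman's rho.
oracle_spearman <- function(x, y) {
  rho_of <- function(a, b) stats::cor(rank(a), rank(b))
  r_obs <- rho_of(x, y)
  perms <- permutations_of(seq_along(y))
  r_all <- apply(perms, 1, function(idx) rho_of(x, y[idx]))
  list(rho = r_obs, p = mean(abs(r_all) >= abs(r_obs) - 1e-12))
}

permutations_of <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], permutations_of(v[-i]))
  }))
}

# Random HMM instance for property tests.
random_hmm_instance <- function(T_max = 8, K_max = 3) {
  K <- sample(1:K_max, 1)
  T_ <- sample(3:T_max, 1)
  init <- as.numeric(stats::runif(K)); init <- init / sum(init)
  tb <- matrix(stats::runif(K * K, 0.05, 1), K, K)
  tb <- tb / rowSums(tb)
  list(K = K, T_ = T_, init = init, trans_base = tb,
       means = stats::rnorm(K, sd = 2),
       sds = stats::runif(K, 0.5, 2),
       x = stats::rnorm(T_, sd = 2))
}
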