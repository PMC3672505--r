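# Independent oracles and small fixtures shared across test files.
# The oracles deliberately use plain loops and pattern enumeration, never
# the package's own vectorized likelihood code.

# log-likelihood of a latent class model by direct summation per row
oracle_lca_loglik <- function(X, lambda, pi) {
  ll <- 0
  for (i in seq_len(nrow(X))) {
    li <- 0
    for (k in seq_along(lambda)) {
      f <- unname(lambda[k])
      for (j in seq_len(ncol(X))) {
        if (!is.na(X[i, j])) f <- f * pi[k, j, X[i, j] + 1]
      }
      li <- li + f
    }
    ll <- ll + log(li)
  }
  ll
}

# log-likelihood of a two-wave transition model by enumeration over (a, b)
oracle_lta_loglik <- function(X1, X2, arm, delta, tau, pi1, pi2) {
  K <- length(delta)
  ll <- 0
  for (i in seq_len(nrow(X1))) {
    tg <- tau[[as.character(arm[i])]]
    li <- 0
    for (a in seq_len(K)) for (b in seq_len(K)) {
      f <- unname(delta[a]) * tg[a, b]
      for (j in seq_len(ncol(X1)))
        if (!is.na(X1[i, j])) f <- f * pi1[a, j, X1[i, j] + 1]
      for (j in seq_len(ncol(X2)))
        if (!is.na(X2[i, j])) f <- f * pi2[b, j, X2[i, j] + 1]
      li <- li + f
    }
    ll <- ll + log(li)
  }
  ll
}

# small deterministic two-class measurement model over `J` items
toy_pi <- function(K = 2, J = 3) {
  pi <- array(NA_real_, c(K, J, 3))
  for (k in seq_len(K)) for (j in seq_len(J)) {
    p <- c(4 - k + j %% 2, k, k + j %% 3) + 0.5
    pi[k, j, ] <- p / sum(p)
  }
  pi
}

# aligned two-wave indicator matrices for a generated trial cohort
make_trial_waves <- function(n, seed, cohort = "trial", config = NULL) {
  cfg <- config %||% default_study_config(n = n, cohort = cohort, seed = seed)
  cfg$n <- as.integer(n); cfg$seed <- as.integer(seed)
  sc <- generate_cohort(cfg)
  al <- align_waves(recode_cohort(sc$cohort))
  al$truth <- sc$truth
  al
}

# default config with identity transitions in both arms
identity_tau_config <- function(n, seed) {
  cfg <- default_study_config(n = n, seed = seed)
  cfg$tau$control <- diag(4)
  cfg$tau$PEI <- diag(4)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
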