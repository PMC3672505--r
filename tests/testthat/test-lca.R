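test_that("one-class model has the closed-form marginal-frequency MLE", {
  al <- make_trial_waves(300, seed = 6)
  fit <- lca_fit(al$x1, K = 1, n_starts = 2, seed = 1)
  expect_equal(unname(fit$lambda), 1)
  for (j in 1:7) {
    freq <- tabulate(al$x1[, j] + 1L, 3) / nrow(al$x1)
    expect_equal(unname(fit$pi[1, j, ]), freq, tolerance = 1e-5)
  }
  post <- posterior_probs(fit, al$x1)
  expect_true(all(post$p == 1))
})

test_that("EM log-likelihood matches the pattern-enumeration oracle and is monotone", {
  set.seed(42)
  pi_true <- toy_pi(K = 2, J = 3)
  cls <- sample(1:2, 30, replace = TRUE)
  X <- sapply(1:3, function(j)
    apply(pi_true[cls, j, ], 1, function(p) sample(0:2, 1, prob = p)))
  X[1, 2] <- NA  # exercise the missing-data factor drop
  fit <- lca_fit(X, K = 2, n_starts = 12, seed = 7)
  expect_equal(fit$loglik, oracle_lca_loglik(X, fit$lambda, fit$pi),
               tolerance = 1e-8)
  expect_true(all(diff(fit$trace) > -1e-8))
  # relabeled output identical across start seeds
  fit2 <- lca_fit(X, K = 2, n_starts = 12, seed = 1234)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit$lambda, fit2$lambda, tolerance = 1e-4)
})

test_that("posteriors match hand arithmetic and degrade gracefully", {
  pi <- array(NA_real_, c(2, 2, 3))
  pi[1, 1, ] <- c(0.7, 0.2, 0.1); pi[1, 2, ] <- c(0.6, 0.3, 0.1)
  pi[2, 1, ] <- c(0.1, 0.3, 0.6); pi[2, 2, ] <- c(0.2, 0.2, 0.6)
  model <- structure(list(K = 2L, lambda = c(0.5, 0.5), pi = pi,
                          n_params = 9L), class = "lca_model")
  x <- matrix(c(0L, 2L), 1, 2)
  # p_k = lambda_k pi_k1(0) pi_k2(2), normalized
  num <- c(0.5 * 0.7 * 0.1, 0.5 * 0.1 * 0.6)
  post <- posterior_probs(model, x)
  expect_equal(drop(post$p), num / sum(num), tolerance = 1e-12)
  # all-missing row is uninformative
  expect_warning(pu <- posterior_probs(model, matrix(NA_integer_, 1, 2)),
                 "all items missing")
  expect_equal(drop(pu$p), c(0.5, 0.5))
})

test_that("entropy has the documented closed form and limits", {
  K <- 3
  uni <- matrix(1 / K, 10, K)
  expect_equal(classification_entropy(uni), 0)
  deg <- diag(K)[c(1, 2, 3, 1), ]
  expect_equal(classification_entropy(deg), 1)
  p <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  hand <- 1 - (-(0.9 * log(0.9) + 0.1 * log(0.1)) +
               -(0.6 * log(0.6) + 0.4 * log(0.4))) / (2 * log(2))
  expect_equal(classification_entropy(p), hand, tolerance = 1e-12)
  expect_warning(e1 <- classification_entropy(matrix(1, 5, 1), K = 1),
                 "K=1")
  expect_equal(e1, 1)
})

test_that("classification table averages posteriors by modal class", {
  p <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.3, 0.7))
  post <- structure(list(p = p, modal = max.col(p, ties.method = "first"),
                         K = 2L), class = "lca_posterior")
  tab <- classification_table(post)
  expect_equal(tab[1, ], c(0.85, 0.15))
  expect_equal(tab[2, ], c(0.3, 0.7))
  expect_equal(rowSums(tab), c(1, 1))
  deg <- structure(list(p = diag(2), modal = 1:2, K = 2L),
                   class = "lca_posterior")
  expect_equal(classification_table(deg), diag(2))
})

test_that("perfectly separated classes give degenerate posteriors and entropy 1", {
  X <- rbind(matrix(0L, 25, 4), matrix(2L, 25, 4))
  fit <- lca_fit(X, K = 2, n_starts = 6, seed = 3)
  post <- posterior_probs(fit, X)
  expect_true(all(pmax(post$p[, 1], post$p[, 2]) > 0.9999))
  expect_gt(classification_entropy(post), 0.999)
})

test_that("parameters are recovered on a large baseline cohort", {
  al <- make_trial_waves(50000, seed = 61, cohort = "baseline")
  cfg <- default_study_config(n = 2, cohort = "baseline")
  fit <- lca_fit(al$x1, K = 4, n_starts = 12, seed = 5)
  expect_true(all(abs(fit$lambda - cfg$lambda0) < 0.02))
  expect_true(max(abs(fit$pi - cfg$profiles)) < 0.02)
})

test_that("model selection table has the nesting and counting properties", {
  al <- make_trial_waves(800, seed = 77)
  sel <- select_models(al$x1, K_range = 2:4, n_starts = 8, seed = 10)
  expect_true(all(diff(sel$loglik) >= -1e-6))
  # each extra class adds 1 + sum_j (C_j - 1) = 15 parameters
  expect_true(all(diff(sel$n_params) == 15))
  expect_true(all(sel$entropy >= 0 & sel$entropy <= 1))
  # index formulas consistent with loglik and d
  expect_equal(sel$AIC, -2 * sel$loglik + 2 * sel$n_params)
  expect_equal(sel$BIC, -2 * sel$loglik + sel$n_params * log(nrow(al$x1)))
  expect_equal(sel$aBIC,
               -2 * sel$loglik + sel$n_params * log((nrow(al$x1) + 2) / 24))
})

test_that("lca_fit guards identifiability and blrt guards its inputs", {
  X <- matrix(rep(c(0L, 2L), each = 10), ncol = 1)
  expect_error(lca_fit(cbind(X, X), K = 3, n_starts = 2, seed = 1),
               "distinct observed patterns")
  al <- make_trial_waves(200, seed = 15)
  expect_error(blrt(al$x1, K = 2, n_boot = 0), "n_boot")
  expect_error(blrt(al$x1, K = 1, n_boot = 10), "K must be")
})

test_that("blrt separates two well-separated classes from one", {
  set.seed(8)
  X <- rbind(matrix(0L, 40, 4), matrix(2L, 40, 4))
  flip <- matrix(rbinom(length(X), 1, 0.05) == 1, nrow(X))  # slight noise
  X[flip] <- 1L
  b <- blrt(X, K = 2, n_boot = 19, seed = 8, n_starts = 6)
  expect_equal(b$p_value, 1 / 20, tolerance = 1e-12)  # at the correction floor
  expect_gt(b$statistic, qchisq(0.999, df = 9))
})
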