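test_that("two-class RRR with one binary covariate equals the cross-product ratio", {
  set.seed(21)
  x <- rbinom(400, 1, 0.5)
  cls <- rbinom(400, 1, plogis(-0.3 + 0.9 * x)) + 1
  fit <- multinomial_rrr(cls, data.frame(x = x), reference = 1)
  tab <- table(cls, x)
  cpr <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_equal(fit$estimates$rrr[fit$estimates$term == "x"], cpr,
               tolerance = 1e-4)
  expect_equal(fit$df, 1)
  expect_gt(fit$lr_chisq, 0)
})

test_that("multinomial fit matches an independent direct optimizer", {
  set.seed(33)
  n <- 20
  covs <- data.frame(x = rnorm(n), z = rbinom(n, 1, 0.5))
  cls <- sample(1:3, n, replace = TRUE)
  fit <- multinomial_rrr(cls, covs, reference = 1)
  # independent oracle: BFGS on the multinomial log-likelihood
  X <- cbind(1, covs$x, covs$z)
  nll <- function(beta) {
    B <- matrix(beta, ncol = 2)           # coefficients for classes 2 and 3
    eta <- cbind(0, X %*% B)
    -sum(eta[cbind(1:n, cls)] - log(rowSums(exp(eta))))
  }
  op <- optim(rep(0, 6), nll, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(fit$loglik, -op$value, tolerance = 1e-6)
})

test_that("rrr stage detects degenerate inputs", {
  expect_error(multinomial_rrr(rep(1, 10), data.frame(x = rnorm(10))),
               "at least 2 classes")
  set.seed(3)
  x <- c(rep(0, 10), rep(1, 10))
  cls <- c(rep(1, 10), rep(2, 10))  # x separates the classes perfectly
  expect_error(multinomial_rrr(cls, data.frame(x = x)), "separation")
})

test_that("saturated logit reproduces cell proportions and AME equals the raw difference", {
  set.seed(55)
  n <- 600
  arm <- sample(c("control", "PEI"), n, replace = TRUE)
  cls <- sample(1:3, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * (arm == "PEI") + 0.2 * cls))
  fit <- lowrisk_glm(y, arm, cls)
  pr <- fitted(fit$glm)
  for (g in c("control", "PEI")) for (k in 1:3) {
    i <- which(arm == g & cls == k)
    expect_equal(unname(pr[i][1]), mean(y[i]), tolerance = 1e-9)
  }
  ame <- average_marginal_effects(fit)
  for (k in 1:3) {
    i1 <- which(arm == "PEI" & cls == k)
    i0 <- which(arm == "control" & cls == k)
    raw <- mean(y[i1]) - mean(y[i0])
    expect_equal(ame$dydx[ame$class == k], raw, tolerance = 1e-9)
  }
  expect_true(all(ame$se > 0))
  expect_true(all(abs(ame$dydx) <= 1))
  expect_true(all(ame$ci_lo <= ame$dydx & ame$dydx <= ame$ci_hi))
  # odds ratio within class k from the saturated fit equals the empirical OR
  ors <- arm_odds_ratios(fit)
  for (k in 1:3) {
    i1 <- which(arm == "PEI" & cls == k)
    i0 <- which(arm == "control" & cls == k)
    emp <- (mean(y[i1]) / (1 - mean(y[i1]))) /
           (mean(y[i0]) / (1 - mean(y[i0])))
    expect_equal(ors$or[ors$class == k], emp, tolerance = 1e-7)
  }
})

test_that("equal transition matrices across arms give near-zero interactions", {
  cfg <- default_study_config(n = 20000, seed = 71)
  cfg$tau$PEI <- cfg$tau$control   # null intervention effect
  cfg$dropout[, "PEI"] <- cfg$dropout[, "control"]
  al <- make_trial_waves(20000, seed = 71, config = cfg)
  fit <- lta_fit(al$x1, al$x2, al$arm, K = 4, n_starts = 2, seed = 12)
  post <- lta_posterior(fit, al$x1, al$x2, al$arm)
  has_f <- rowSums(!is.na(al$x2)) > 0
  y <- ifelse(has_f, as.integer(post$modal_w2 == 1L), NA_integer_)
  gfit <- lowrisk_glm(y, al$arm, post$modal_w1)
  sm <- summary(gfit$glm)$coefficients
  inter <- grepl(":", rownames(sm))
  expect_true(all(abs(sm[inter, "z value"]) < 3))
  ame <- average_marginal_effects(gfit)
  expect_true(all(abs(ame$dydx) < 0.05))
})

test_that("glm stage errors on an empty arm-by-class cell and tiny classes warn", {
  y <- rbinom(40, 1, 0.5)
  arm <- rep(c("control", "PEI"), each = 20)
  cls <- c(rep(1, 20), rep(2, 20))   # class 1 never appears in PEI
  expect_error(lowrisk_glm(y, arm, cls), "empty arm-by-class cell")
  set.seed(4)
  arm2 <- sample(c("control", "PEI"), 40, replace = TRUE)
  fit <- lowrisk_glm(y, arm2, rep(1:2, 20))
  expect_warning(ame <- average_marginal_effects(fit, classes = "9"),
                 "fewer than 2 subjects")
  expect_true(is.nan(ame$dydx[ame$class == "9"]))
})

test_that("attrition chi-square matches the hand formula and its symmetries", {
  ret <- rep(c(TRUE, FALSE, TRUE, FALSE), c(90, 10, 80, 20))
  arm <- rep(c("control", "PEI"), each = 100)
  r <- attrition_test(!ret, arm)   # "did not return" orientation
  # sum (O - E)^2 / E on the 2x2 with margins 100/100 and 30/170
  hand <- (10 - 15)^2 / 15 + (90 - 85)^2 / 85 +
          (20 - 15)^2 / 15 + (80 - 85)^2 / 85
  expect_equal(r$statistic, hand, tolerance = 1e-10)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pchisq(hand, 1, lower.tail = FALSE))
  # swapping rows and columns simultaneously leaves the statistic unchanged
  r2 <- attrition_test(ret, factor(arm, c("PEI", "control")))
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-10)
  # equal proportions give a zero statistic
  r0 <- attrition_test(rep(c(TRUE, FALSE), 50), rep(c("a", "b"), each = 50))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(attrition_test(rep(TRUE, 200), arm), "zero margin")
})

test_that("participation test has df K-1 and detects nothing under the null", {
  cls <- rep(1:4, each = 50)
  rnd <- rep(c(TRUE, FALSE), 100)
  r <- participation_bias_test(cls, rnd)
  expect_equal(r$df, 3)
  expect_equal(r$statistic, 0, tolerance = 1e-10)
  expect_error(participation_bias_test(cls, rep(TRUE, 200)), "zero margin")
})
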