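# Post-classification ("classify-analyze") stage: participants are assigned
# their most likely class and class membership is treated as observed in
# downstream regressions, as in the trial's analysis. No classification
# uncertainty is propagated (a documented limitation).

#' Multinomial logistic regression of class membership on covariates
#'
#' Fits a maximum-likelihood multinomial logit predicting most likely class
#' membership from covariates and reports relative-risk ratios
#' (exponentiated coefficients) with normal-approximation 95% confidence
#' intervals, plus the model likelihood-ratio chi-square against the
#' intercept-only model.
#'
#' @param class Integer or factor of modal class assignments.
#' @param covariates A data.frame of predictors.
#' @param reference Reference class (level) for the outcome.
#' @return List of class `rrr_fit`: `estimates` (data.frame with `class`,
#'   `term`, `rrr`, `ci_lo`, `ci_hi`, `z`, `p`), `lr_chisq`, `df`,
#'   `p_model`, `loglik`, and the underlying `nnet::multinom` fit.
#' @export
multinomial_rrr <- function(class, covariates, reference = 1) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(class))
  y <- factor(class)
  if (nlevels(y) < 2) stop("need at least 2 classes present")
  if (any(table(y) == 0)) stop("empty class level present")
  y <- stats::relevel(y, ref = as.character(reference))
  dat <- data.frame(.class = y, covariates)
  fit <- nnet::multinom(.class ~ ., data = dat, trace = FALSE, maxit = 1000,
                        reltol = 1e-12, abstol = 1e-12)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, 1, dimnames = list(levels(y)[2], names(cf)))
  big <- which(abs(cf) > 15, arr.ind = TRUE)
  if (nrow(big))
    stop("perfect separation detected for covariate ", colnames(cf)[big[1, 2]])
  sm <- summary(fit)
  se <- sm$standard.errors
  if (is.null(dim(se))) se <- matrix(se, 1, dimnames = dimnames(cf))
  est <- do.call(rbind, lapply(rownames(cf), function(cl) {
    terms <- setdiff(colnames(cf), "(Intercept)")
    data.frame(class = cl, term = terms,
               rrr = exp(cf[cl, terms]),
               ci_lo = exp(cf[cl, terms] - 1.96 * se[cl, terms]),
               ci_hi = exp(cf[cl, terms] + 1.96 * se[cl, terms]),
               z = cf[cl, terms] / se[cl, terms],
               p = 2 * stats::pnorm(-abs(cf[cl, terms] / se[cl, terms])),
               row.names = NULL)
  }))
  null_fit <- nnet::multinom(.class ~ 1, data = dat, trace = FALSE,
                             maxit = 1000, reltol = 1e-12, abstol = 1e-12)
  lr <- 2 * (as.numeric(stats::logLik(fit)) - as.numeric(stats::logLik(null_fit)))
  df <- attr(stats::logLik(fit), "df") - attr(stats::logLik(null_fit), "df")
  structure(list(estimates = est, lr_chisq = lr, df = df,
                 p_model = stats::pchisq(lr, df, lower.tail = FALSE),
                 loglik = as.numeric(stats::logLik(fit)), fit = fit),
            class = "rrr_fit")
}

#' Logit model for low-risk membership at follow-up
#'
#' Fits the trial's effect model: a binomial GLM with logit link for the
#' follow-up low-risk indicator, with intervention arm, most likely
#' baseline class, and their interaction as predictors, plus optional
#' adjustment covariates. Rows with a missing outcome (no follow-up) are
#' dropped and counted; every arm-by-class cell must be non-empty.
#'
#' @param outcome Logical/0-1 vector: member of the low-risk class at
#'   follow-up (`NA` for participants without follow-up).
#' @param arm Factor or character arm labels.
#' @param baseline_class Integer or factor of modal baseline classes.
#' @param covariates Optional data.frame of adjustment covariates.
#' @param control Reference arm level; defaults to a level named
#'   `"control"` when present, otherwise the first factor level.
#' @return Object of class `lowrisk_fit`: the `glm` fit plus the analysis
#'   frame and bookkeeping (`n`, `n_dropped`).
#' @export
lowrisk_glm <- function(outcome, arm, baseline_class, covariates = NULL,
                        control = NULL) {
  arm <- as.factor(arm)
  ref <- control %||% (if ("control" %in% levels(arm)) "control"
                       else levels(arm)[1])
  arm <- stats::relevel(arm, ref = ref)
  cls <- as.factor(baseline_class)
  n0 <- length(outcome)
  stopifnot(length(arm) == n0, length(cls) == n0)
  keep <- !is.na(outcome)
  dat <- data.frame(.y = as.integer(outcome[keep]),
                    .arm = droplevels(arm[keep]),
                    .class = droplevels(cls[keep]))
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == n0)
    dat <- cbind(dat, covariates[keep, , drop = FALSE])
  }
  cells <- table(dat$.arm, dat$.class)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty arm-by-class cell: arm=%s, class=%s",
                 rownames(cells)[idx[1]], colnames(cells)[idx[2]]))
  }
  form <- if (is.null(covariates)) .y ~ .arm * .class
          else stats::as.formula(paste(".y ~ .arm * .class +",
                                       paste(names(covariates), collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  structure(list(glm = fit, data = dat,
                 arm_levels = levels(dat$.arm),
                 class_levels = levels(dat$.class),
                 n = nrow(dat), n_dropped = n0 - nrow(dat)),
            class = "lowrisk_fit")
}

#' @export
print.lowrisk_fit <- function(x, ...) {
  cat(sprintf("<lowrisk_fit> binomial logit, n=%d (%d without follow-up dropped)\n",
              x$n, x$n_dropped))
  print(stats::coef(x$glm))
  invisible(x)
}

.predict_arm <- function(fit, arm_value) {
  nd <- fit$data
  nd$.arm <- factor(arm_value, levels = fit$arm_levels)
  list(X = stats::model.matrix(stats::terms(fit$glm), nd),
       eta = NULL)
}

#' Average marginal effect of arm within each baseline class
#'
#' For each baseline class, the average marginal effect (AME) of the
#' intervention is the mean, over the subjects modally assigned to that
#' class, of the difference in predicted probability of follow-up low-risk
#' membership with arm switched to the intervention versus the control
#' level, holding each subject's other covariates at their observed values
#' (the `dy/dx` average-over-subjects convention). Standard errors use the
#' delta method over the full coefficient covariance; confidence intervals
#' are `estimate +/- 1.96 SE`.
#'
#' @param fit A [lowrisk_glm()] fit.
#' @param classes Baseline classes to report (default: all).
#' @return data.frame of class `ame_table`: `class`, `dydx`, `se`, `ci_lo`,
#'   `ci_hi`, `z`, `p`, `n`.
#' @export
average_marginal_effects <- function(fit, classes = NULL) {
  stopifnot(inherits(fit, "lowrisk_fit"))
  if (length(fit$arm_levels) != 2)
    stop("average marginal effects require exactly two arms")
  classes <- classes %||% fit$class_levels
  b <- stats::coef(fit$glm)
  V <- stats::vcov(fit$glm)
  X1 <- .predict_arm(fit, fit$arm_levels[2])$X
  X0 <- .predict_arm(fit, fit$arm_levels[1])$X
  rows <- lapply(as.character(classes), function(cl) {
    i <- which(fit$data$.class == cl)
    if (length(i) < 2) {
      warning(sprintf("fewer than 2 subjects in baseline class %s; AME undefined", cl))
      return(data.frame(class = cl, dydx = NaN, se = NaN, ci_lo = NaN,
                        ci_hi = NaN, z = NaN, p = NaN, n = length(i)))
    }
    eta1 <- drop(X1[i, , drop = FALSE] %*% b)
    eta0 <- drop(X0[i, , drop = FALSE] %*% b)
    ame <- mean(stats::plogis(eta1) - stats::plogis(eta0))
    grad <- colMeans(stats::dlogis(eta1) * X1[i, , drop = FALSE] -
                       stats::dlogis(eta0) * X0[i, , drop = FALSE])
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    z <- ame / se
    data.frame(class = cl, dydx = ame, se = se,
               ci_lo = ame - 1.96 * se, ci_hi = ame + 1.96 * se,
               z = z, p = 2 * stats::pnorm(-abs(z)), n = length(i),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ame_table", "data.frame")
  out
}

#' Odds ratio of the arm effect within each baseline class
#'
#' Exponentiates the arm effect at each baseline class (arm main effect
#' plus the arm-by-class interaction) to an odds ratio with a Wald 95%
#' confidence interval; `100 * (OR - 1)` is the percent increase in the
#' odds of follow-up low-risk membership under the intervention.
#'
#' @param fit A [lowrisk_glm()] fit.
#' @return data.frame: `class`, `log_or`, `or`, `ci_lo`, `ci_hi`,
#'   `pct_odds_increase`.
#' @export
arm_odds_ratios <- function(fit) {
  stopifnot(inherits(fit, "lowrisk_fit"))
  if (length(fit$arm_levels) != 2)
    stop("odds ratios require exactly two arms")
  b <- stats::coef(fit$glm)
  V <- stats::vcov(fit$glm)
  arm_term <- paste0(".arm", fit$arm_levels[2])
  rows <- lapply(seq_along(fit$class_levels), function(ci) {
    cl <- fit$class_levels[ci]
    contrast <- stats::setNames(numeric(length(b)), names(b))
    contrast[arm_term] <- 1
    if (ci > 1) {
      int_term <- paste0(arm_term, ":.class", cl)
      if (!int_term %in% names(b))
        stop("interaction term not found: ", int_term)
      contrast[int_term] <- 1
    }
    lo <- drop(contrast %*% b)
    se <- sqrt(drop(t(contrast) %*% V %*% contrast))
    data.frame(class = cl, log_or = lo, or = exp(lo),
               ci_lo = exp(lo - 1.96 * se), ci_hi = exp(lo + 1.96 * se),
               pct_odds_increase = 100 * (exp(lo) - 1), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Attrition test: return rate by arm within a baseline class
#'
#' Pearson chi-square (1 df, no continuity correction) comparing the
#' proportion not returning for follow-up between arms, typically within
#' the baseline high-risk class.
#'
#' @param returned Logical vector: returned for follow-up.
#' @param arm Two-level factor or character vector.
#' @return List of class `chisq_result`: `statistic`, `df`, `p_value`,
#'   `table`.
#' @export
attrition_test <- function(returned, arm) {
  tab <- table(as.factor(arm), factor(returned, c(FALSE, TRUE)))
  if (nrow(tab) != 2) stop("attrition test requires exactly two arms")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("attrition table has a zero margin")
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, table = tab),
            class = "chisq_result")
}

#' Trial-participation selection test
#'
#' Pearson chi-square (K-1 df) comparing the distribution of modal classes
#' between participants who were randomized to a trial condition and those
#' who were not.
#'
#' @param class Modal class assignments (all baseline participants).
#' @param randomized Logical vector.
#' @return List of class `chisq_result`.
#' @export
participation_bias_test <- function(class, randomized) {
  tab <- table(factor(class), factor(randomized, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("participation table has a zero margin")
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, table = tab),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi^2(%d) = %.3f, p = %.4g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}
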