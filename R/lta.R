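# Two-wave latent transition model.
#
# The observed-data likelihood for participant i in arm g is
#   sum_a sum_b delta_a tau_g[a,b] prod_j pi1[a,j,x1_ij] prod_j pi2[b,j,x2_ij]
# with missing item factors dropped; a participant with no follow-up record
# contributes the b-marginalized wave-1 factor only. Estimation is EM over
# collapsed (wave-1 pattern, wave-2 pattern, arm) cells, so the cost per
# iteration grows with the number of distinct cells, not N.

#' Constraint specification for a latent transition model
#'
#' @param time_invariant Logical; if `TRUE` (default) the item-response
#'   probabilities are equal at both waves ("thresholds constrained over
#'   time"), stored as one shared table.
#' @param free_classes Integer vector of classes whose wave-2 item-response
#'   rows are freed (partial non-invariance); ignored (all free) when
#'   `time_invariant = FALSE`. Class indices refer to the canonical risk
#'   order of the warm start.
#' @param arm_invariant_measurement Logical; if `TRUE` (default, the
#'   accepted model) the measurement model is shared across trial arms; if
#'   `FALSE` each arm gets its own table (the "unconstrained across arms"
#'   comparison model; requires full time invariance).
#' @param arm_specific_tau Logical; if `TRUE` (default) each arm has its own
#'   transition matrix (the intervention enters as a known class).
#' @return List of class `lta_constraints`.
#' @export
lta_constraints <- function(time_invariant = TRUE, free_classes = integer(0),
                            arm_invariant_measurement = TRUE,
                            arm_specific_tau = TRUE) {
  if (!time_invariant) free_classes <- NULL  # resolved to all classes at fit time
  if (!arm_invariant_measurement &&
      (!time_invariant || length(free_classes)))
    stop("arm-specific measurement is supported only with full time invariance")
  structure(list(time_invariant = time_invariant,
                 free_classes = free_classes,
                 arm_invariant_measurement = arm_invariant_measurement,
                 arm_specific_tau = arm_specific_tau),
            class = "lta_constraints")
}

.lta_n_params <- function(K, J, G, cons, free) {
  d_delta <- K - 1
  d_tau <- K * (K - 1) * (if (cons$arm_specific_tau) G else 1)
  d_meas <- if (cons$arm_invariant_measurement) {
    K * J * 2 + length(free) * J * 2
  } else {
    G * K * J * 2
  }
  as.integer(d_delta + d_tau + d_meas)
}

.lta_em_once <- function(dat, K, cons, free, init, max_iter, tol) {
  # dat: list per arm with X1, X2, w, Ind1, Ind2
  G <- length(dat); J <- ncol(dat[[1]]$X1)
  delta <- init$delta
  tau <- init$tau            # list length G (shared object replicated if pooled)
  pis <- init$pis            # list per arm (identical when arm-invariant): K x J x 3
  pi2f <- init$pi2f          # K x J x 3 wave-2 free rows (used for classes in `free`)
  n <- sum(vapply(dat, function(d) sum(d$w), 0))
  trace <- numeric(0); ll_old <- -Inf; converged <- FALSE

  pi2_of <- function(g) {
    p2 <- pis[[g]]
    if (length(free)) p2[free, , ] <- pi2f[free, , ]
    p2
  }

  for (it in seq_len(max_iter)) {
    ll <- 0
    es <- vector("list", G)
    for (g in seq_len(G)) {
      d <- dat[[g]]
      A <- .pattern_probs(d$X1, pis[[g]])
      B <- .pattern_probs(d$X2, pi2_of(g))
      Ad <- A * rep(delta, each = nrow(A))
      Cm <- B %*% t(tau[[g]])
      lik <- rowSums(Ad * Cm)
      ll <- ll + sum(d$w * log(lik))
      wl <- d$w / lik
      r1 <- Ad * Cm * wl                       # weighted responsibilities
      r2 <- B * (Ad %*% tau[[g]]) * wl
      Tg <- crossprod(Ad * wl, B) * tau[[g]]   # weighted joint (a,b) mass
      es[[g]] <- list(r1 = r1, r2 = r2, Tg = Tg)
    }
    trace <- c(trace, ll)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    # M-step
    delta <- Reduce(`+`, lapply(es, function(e) colSums(e$r1))) / n
    if (cons$arm_specific_tau) {
      for (g in seq_len(G)) {
        Tg <- es[[g]]$Tg
        tau[[g]] <- pmax(Tg, 1e-12) / rowSums(pmax(Tg, 1e-12))
      }
    } else {
      Tg <- Reduce(`+`, lapply(es, function(e) e$Tg))
      t1 <- pmax(Tg, 1e-12) / rowSums(pmax(Tg, 1e-12))
      for (g in seq_len(G)) tau[[g]] <- t1
    }
    if (cons$arm_invariant_measurement) {
      cnt1 <- array(0, c(K, J, 3)); cnt2 <- array(0, c(K, J, 3))
      for (g in seq_len(G)) {
        d <- dat[[g]]; e <- es[[g]]
        for (j in seq_len(J)) {
          cnt1[, j, ] <- cnt1[, j, ] + crossprod(e$r1, d$Ind1[[j]])
          cnt2[, j, ] <- cnt2[, j, ] + crossprod(e$r2, d$Ind2[[j]])
        }
      }
      pi_new <- pis[[1]]
      for (j in seq_len(J)) {
        pooled <- cnt1[, j, ] + cnt2[, j, ]
        if (length(free)) pooled[free, ] <- cnt1[free, j, ]
        pi_new[, j, ] <- .normalize_pi(pooled)
        if (length(free))
          pi2f[free, j, ] <- .normalize_pi(cnt2[, j, ])[free, , drop = FALSE]
      }
      for (g in seq_len(G)) pis[[g]] <- pi_new
    } else {
      for (g in seq_len(G)) {
        d <- dat[[g]]; e <- es[[g]]
        for (j in seq_len(J)) {
          cnt <- crossprod(e$r1, d$Ind1[[j]]) + crossprod(e$r2, d$Ind2[[j]])
          pis[[g]][, j, ] <- .normalize_pi(cnt)
        }
      }
    }
  }
  list(delta = delta, tau = tau, pis = pis, pi2f = pi2f,
       loglik = trace[length(trace)], trace = trace,
       converged = converged, n_iter = length(trace))
}

.random_lta_start <- function(K, J, G, warm = NULL) {
  if (is.null(warm)) {
    s <- .random_lca_start(K, J)
    delta <- s$lambda; pi0 <- s$pi
  } else {
    delta <- warm$lambda + stats::runif(K, 0, 0.05)
    delta <- delta / sum(delta)
    noise <- array(stats::runif(K * J * 3, 0, 0.05), c(K, J, 3))
    pi0 <- warm$pi + noise
    pi0 <- pi0 / rep(apply(pi0, c(1, 2), sum), times = 3)
  }
  tau1 <- function() {
    m <- matrix(stats::runif(K * K, 0.5, 1.5), K, K) + diag(K)
    m / rowSums(m)
  }
  list(delta = delta,
       tau = lapply(seq_len(G), function(g) tau1()),
       pis = lapply(seq_len(G), function(g) pi0),
       pi2f = pi0)
}

.lta_prepare <- function(x1, x2, arm) {
  X1 <- .as_indicator_values(x1)
  X2 <- .as_indicator_values(x2)
  stopifnot(nrow(X1) == nrow(X2), nrow(X1) == length(arm),
            ncol(X1) == ncol(X2))
  if (any(rowSums(!is.na(X1)) == 0))
    stop("every participant must have wave-1 item data")
  arm <- as.factor(arm)
  list(X1 = X1, X2 = X2, arm = arm)
}

#' Fit a two-wave latent transition model
#'
#' Maximum-likelihood estimation (EM, multiple starts) of a `K`-class
#' latent transition model with trial arm as a known class: wave-1 class
#' probabilities `delta`, per-arm transition matrices `tau`, and item
#' response probabilities constrained across waves and arms according to
#' `constraints`. Participants without a follow-up record are retained and
#' their wave-2 factors marginalized out. By default the first start warm
#' starts from a wave-1 latent class fit (canonically ordered), followed by
#' random starts; the best log-likelihood wins and the final solution is
#' relabeled into canonical risk order.
#'
#' @param x1,x2 Wave-1 / wave-2 indicator data, row-aligned by participant
#'   (`NA`-filled rows in `x2` for participants without follow-up).
#' @param arm Factor or character vector of arm labels, one per participant.
#' @param K Number of latent classes.
#' @param constraints An [lta_constraints()] object.
#' @param n_starts Number of EM starts (including the warm start).
#' @param max_iter,tol EM control.
#' @param seed Optional seed (starts and warm-start LCA).
#' @param warm_start Use a wave-1 LCA fit to initialize (default `TRUE`).
#' @param warm_from Optional fitted `lta_model` nested in (or equal to) the
#'   requested model, used as an additional EM start. Starting the general
#'   model of a likelihood-ratio comparison from the restricted solution
#'   guarantees, by EM monotonicity, that the general fit is never worse.
#' @return Object of class `lta_model` with elements `delta`, `tau` (named
#'   list per arm), `pi_w1`, `pi_w2` (equal objects under full invariance;
#'   per-arm lists when measurement varies by arm), `loglik`, `n_params`,
#'   `converged`, `constraints`, `arm_levels`, `arm_freq`, `K`, `n`,
#'   `n_complete`, `trace`, `start_log`.
#' @export
lta_fit <- function(x1, x2, arm, K, constraints = lta_constraints(),
                    n_starts = 10, max_iter = 1000, tol = 1e-7,
                    seed = NULL, warm_start = TRUE, warm_from = NULL) {
  stopifnot(inherits(constraints, "lta_constraints"), K >= 1)
  prep <- .lta_prepare(x1, x2, arm)
  X1 <- prep$X1; X2 <- prep$X2; arm <- prep$arm
  J <- ncol(X1); G <- nlevels(arm)
  if (constraints$arm_specific_tau && any(table(arm) == 0))
    stop("arm-specific transitions requested but arm level(s) absent: ",
         paste(levels(arm)[table(arm) == 0], collapse = ", "))
  free <- if (constraints$time_invariant) {
    fc <- as.integer(constraints$free_classes %||% integer(0))
    if (length(fc) && (any(fc < 1) || any(fc > K)))
      stop("free_classes must name classes in 1..", K)
    sort(unique(fc))
  } else seq_len(K)

  if (!is.null(seed)) set.seed(seed)
  # collapse to unique (x1 pattern, x2 pattern, arm) cells, per arm
  dat <- vector("list", G)
  for (g in seq_len(G)) {
    i <- which(arm == levels(arm)[g])
    pat <- .collapse_patterns(cbind(X1[i, , drop = FALSE],
                                    X2[i, , drop = FALSE]))
    Xp1 <- pat$X[, seq_len(J), drop = FALSE]
    Xp2 <- pat$X[, J + seq_len(J), drop = FALSE]
    ind <- function(Xp, j) {
      m <- matrix(0, nrow(Xp), 3)
      obs <- which(!is.na(Xp[, j]))
      m[cbind(obs, Xp[obs, j] + 1L)] <- 1
      m
    }
    dat[[g]] <- list(X1 = Xp1, X2 = Xp2, w = pat$w,
                     Ind1 = lapply(seq_len(J), function(j) ind(Xp1, j)),
                     Ind2 = lapply(seq_len(J), function(j) ind(Xp2, j)),
                     idx = i, map = pat$map)
  }

  warm <- NULL
  if (warm_start) {
    warm <- lca_fit(X1, K, n_starts = max(2, ceiling(n_starts / 2)),
                    max_iter = max_iter, tol = tol)
  }
  inits <- list()
  if (!is.null(warm_from)) {
    stopifnot(inherits(warm_from, "lta_model"), warm_from$K == K)
    if (is.list(warm_from$pi_w1))
      stop("warm_from requires a model with arm-invariant measurement")
    pi0 <- unname(warm_from$pi_w1); dimnames(pi0) <- NULL
    pi2 <- unname(warm_from$pi_w2); dimnames(pi2) <- NULL
    tau0 <- lapply(levels(arm), function(g)
      unname(warm_from$tau[[g]] %||% warm_from$tau[[1]]))
    inits <- list(list(delta = unname(warm_from$delta), tau = tau0,
                       pis = lapply(seq_len(G), function(g) pi0),
                       pi2f = pi2))
  }

  best <- NULL
  start_log <- data.frame(start = integer(0), loglik = numeric(0),
                          converged = logical(0))
  for (s in seq_len(length(inits) + max(n_starts, 1))) {
    init <- if (s <= length(inits)) inits[[s]] else
      .random_lta_start(K, J, G, warm = if (s == length(inits) + 1) warm else NULL)
    # canonical order of the initial measurement model, so that constraint
    # class indices keep their intended identity during EM
    ord0 <- .risk_order(init$pis[[1]])
    init$delta <- init$delta[ord0]
    init$tau <- lapply(init$tau, function(t) t[ord0, ord0, drop = FALSE])
    init$pis <- lapply(init$pis, function(p) p[ord0, , , drop = FALSE])
    init$pi2f <- init$pi2f[ord0, , , drop = FALSE]
    fit <- .lta_em_once(dat, K, constraints, free, init, max_iter, tol)
    start_log <- rbind(start_log,
                       data.frame(start = s, loglik = fit$loglik,
                                  converged = fit$converged))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!any(start_log$converged))
    stop("no EM start converged within max_iter", call. = FALSE)

  # final canonical relabeling
  ord <- .risk_order(best$pis[[1]])
  delta <- best$delta[ord]
  tau <- lapply(best$tau, function(t) t[ord, ord, drop = FALSE])
  names(tau) <- levels(arm)
  pis <- lapply(best$pis, function(p) p[ord, , , drop = FALSE])
  pi2f <- best$pi2f[ord, , , drop = FALSE]
  free_out <- sort(match(free, ord))

  labs <- .class_labels(K)
  names(delta) <- labs
  for (g in seq_along(tau)) dimnames(tau[[g]]) <- list(labs, labs)
  item_names <- colnames(X1) %||% lta_items()$name[seq_len(J)]
  dimn <- list(labs, item_names, c("c0", "c1", "c2"))
  pi_w1 <- if (constraints$arm_invariant_measurement) pis[[1]] else pis
  pi_w2 <- if (constraints$arm_invariant_measurement) {
    p2 <- pis[[1]]
    if (length(free_out)) p2[free_out, , ] <- pi2f[free_out, , ]
    p2
  } else pis
  if (constraints$arm_invariant_measurement) {
    dimnames(pi_w1) <- dimn; dimnames(pi_w2) <- dimn
  }

  structure(list(
    K = as.integer(K), delta = delta, tau = tau,
    pi_w1 = pi_w1, pi_w2 = pi_w2, free_classes = free_out,
    loglik = best$loglik,
    n_params = .lta_n_params(K, J, G, constraints, free),
    converged = best$converged, constraints = constraints,
    arm_levels = levels(arm),
    arm_freq = as.vector(table(arm)) / length(arm),
    n = nrow(X1), n_complete = sum(rowSums(!is.na(X2)) > 0),
    trace = best$trace, start_log = start_log,
    item_names = item_names
  ), class = "lta_model")
}

#' @export
print.lta_model <- function(x, ...) {
  cat(sprintf("<lta_model> K=%d, N=%d (%d with follow-up), loglik=%.3f, params=%d\n",
              x$K, x$n, x$n_complete, x$loglik, x$n_params))
  cat("delta:", paste(sprintf("%.3f", x$delta), collapse = " "), "\n")
  for (g in names(x$tau)) {
    cat(sprintf("tau[%s]:\n", g))
    print(round(x$tau[[g]], 3))
  }
  invisible(x)
}

.pi_for_arm <- function(pi, g) if (is.list(pi)) pi[[g]] else pi

#' Posterior class probabilities from a latent transition model
#'
#' Marginal wave-1 and wave-2 posterior membership probabilities per
#' participant, given both waves' observed items and arm.
#'
#' @param model An `lta_model`.
#' @param x1,x2,arm As in [lta_fit()].
#' @return List of class `lta_posterior`: `p_w1`, `p_w2` (N x K), `modal_w1`,
#'   `modal_w2` (ties to the lowest class index).
#' @export
lta_posterior <- function(model, x1, x2, arm) {
  prep <- .lta_prepare(x1, x2, arm)
  arm <- factor(prep$arm, levels = model$arm_levels)
  if (any(is.na(arm))) stop("arm labels not seen by the model")
  N <- nrow(prep$X1); K <- model$K
  p1 <- matrix(NA_real_, N, K); p2 <- matrix(NA_real_, N, K)
  for (g in seq_along(model$arm_levels)) {
    i <- which(arm == model$arm_levels[g])
    if (!length(i)) next
    A <- .pattern_probs(prep$X1[i, , drop = FALSE],
                        .pi_for_arm(model$pi_w1, g))
    B <- .pattern_probs(prep$X2[i, , drop = FALSE],
                        .pi_for_arm(model$pi_w2, g))
    tg <- model$tau[[g]]
    Ad <- A * rep(model$delta, each = length(i))
    lik <- rowSums(Ad * (B %*% t(tg)))
    p1[i, ] <- Ad * (B %*% t(tg)) / lik
    p2[i, ] <- B * (Ad %*% tg) / lik
  }
  structure(list(p_w1 = p1, p_w2 = p2,
                 modal_w1 = max.col(p1, ties.method = "first"),
                 modal_w2 = max.col(p2, ties.method = "first"),
                 K = K),
            class = "lta_posterior")
}

#' Model-implied marginal class probabilities per wave
#'
#' Wave 1 is `delta`; wave 2 is the arm-frequency-weighted mixture of
#' `delta' tau_g` over arms.
#'
#' @param model An `lta_model`.
#' @return 2 x K matrix with rows `wave1`, `wave2`.
#' @export
marginal_class_probs <- function(model) {
  w2 <- Reduce(`+`, Map(function(tg, f) f * drop(model$delta %*% tg),
                        model$tau, model$arm_freq))
  rbind(wave1 = model$delta, wave2 = w2)
}

#' Ordinary likelihood ratio test between nested transition models
#'
#' @param restricted,general Fitted `lta_model`s, the restricted model
#'   nested in the general one (fewer parameters).
#' @return List of class `lrt_result`: `statistic` (`-2 dLL`), `df`,
#'   `p_value`.
#' @export
lrt_compare <- function(restricted, general) {
  d0 <- restricted$n_params; d1 <- general$n_params
  if (d1 <= d0) stop("general model must have more parameters than the restricted model")
  stat <- 2 * (general$loglik - restricted$loglik)
  if (stat < -1e-6 * (abs(restricted$loglik) + 1))
    stop("general model has lower log-likelihood than the restricted model: optimization failure")
  stat <- max(stat, 0)
  df <- d1 - d0
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LR chi^2(%d) = %.3f, p = %.4g\n", x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Satorra-Bentler scaled chi-square difference test
#'
#' Given log-likelihoods, scaling correction factors and parameter counts of
#' a nested pair of models estimated with a robust (sandwich) estimator,
#' computes the scaling denominator `cd = (d0*c0 - d1*c1) / (d0 - d1)`, the
#' scaled difference statistic `TRd = -2 (L0 - L1) / cd`, and a p-value from
#' the chi-square distribution with `d1 - d0` degrees of freedom. With
#' `c0 = c1 = 1` this reduces exactly to the ordinary likelihood ratio test.
#' A non-positive `cd` (a known pathology of the test) is an error.
#'
#' @param L0,c0,d0 Restricted model: log-likelihood, scaling factor,
#'   parameter count.
#' @param L1,c1,d1 General model (`d1 > d0`).
#' @return List of class `sb_diff_result`: `TRd`, `cd`, `df`, `p_value`.
#' @export
#' @examples
#' sb_scaled_difference(-5000, 1.2, 10, -4980, 1.3, 20)
sb_scaled_difference <- function(L0, c0, d0, L1, c1, d1) {
  if (d0 == d1) stop("models have equal parameter counts; difference test undefined")
  if (d1 < d0) stop("the general model (L1, c1, d1) must have more parameters")
  if (c0 <= 0 || c1 <= 0) stop("scaling correction factors must be positive")
  cd <- (d0 * c0 - d1 * c1) / (d0 - d1)
  if (cd <= 0)
    stop(sprintf("scaling denominator cd = %.4f is not positive; scaled difference test undefined",
                 cd))
  TRd <- -2 * (L0 - L1) / cd
  df <- d1 - d0
  structure(list(TRd = TRd, cd = cd, df = df,
                 p_value = stats::pchisq(TRd, df, lower.tail = FALSE)),
            class = "sb_diff_result")
}

#' @export
print.sb_diff_result <- function(x, ...) {
  cat(sprintf("SB scaled difference: TRd = %.3f (cd = %.4f), df = %d, p = %.4g\n",
              x$TRd, x$cd, x$df, x$p_value))
  invisible(x)
}
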