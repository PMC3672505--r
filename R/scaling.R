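# Scaling correction factor c = trace(A^-1 B) / d for a fitted mixture
# model, where A is the observed average information (minus the Hessian of
# the average log-likelihood) and B the average outer product of
# per-observation scores. Under correct specification A ~ B and c ~ 1;
# under misspecification c feeds the Satorra-Bentler scaled difference
# test. Derivatives are taken numerically in an unconstrained softmax
# parameterization (first category / class as reference).

.softmax1 <- function(eta) {
  # eta: free logits; returns probabilities with reference prepended
  e <- exp(c(0, eta))
  e / sum(e)
}

.logits1 <- function(p) log(p[-1] / p[1])

.pack_rows <- function(mat) as.vector(t(log(mat[, -1, drop = FALSE] / mat[, 1])))

.unpack_rows <- function(theta, nrow, ncol) {
  m <- matrix(theta, nrow = nrow, byrow = TRUE)
  t(apply(m, 1, function(eta) .softmax1(eta)))
}

.pack_pi <- function(pi) {
  K <- dim(pi)[1]; J <- dim(pi)[2]
  out <- numeric(0)
  for (k in seq_len(K)) for (j in seq_len(J))
    out <- c(out, .logits1(pi[k, j, ]))
  out
}

.unpack_pi <- function(theta, K, J, C = 3L) {
  pi <- array(NA_real_, c(K, J, C))
  idx <- 1L
  for (k in seq_len(K)) for (j in seq_len(J)) {
    pi[k, j, ] <- .softmax1(theta[idx:(idx + C - 2L)])
    idx <- idx + C - 1L
  }
  pi
}

.sandwich_c <- function(f_vec, theta, w, d_expected) {
  d <- length(theta)
  if (d != d_expected)
    stop(sprintf("parameter vector length (%d) does not match the model's parameter count (%d)",
                 d, d_expected))
  n <- sum(w)
  h <- 1e-5
  base <- f_vec(theta)
  P <- length(base)
  S <- matrix(NA_real_, P, d)
  for (i in seq_len(d)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    S[, i] <- (f_vec(tp) - f_vec(tm)) / (2 * h)
  }
  B <- crossprod(S * w, S) / n

  hh <- 1e-4
  f_tot <- function(th) sum(w * f_vec(th))
  f0 <- f_tot(theta)
  H <- matrix(NA_real_, d, d)
  fp <- numeric(d); fm <- numeric(d)
  for (i in seq_len(d)) {
    tp <- theta; tp[i] <- tp[i] + hh
    tm <- theta; tm[i] <- tm[i] - hh
    fp[i] <- f_tot(tp); fm[i] <- f_tot(tm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / hh^2
  }
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (j <= i) next
    tpp <- theta; tpp[i] <- tpp[i] + hh; tpp[j] <- tpp[j] + hh
    tpm <- theta; tpm[i] <- tpm[i] + hh; tpm[j] <- tpm[j] - hh
    tmp <- theta; tmp[i] <- tmp[i] - hh; tmp[j] <- tmp[j] + hh
    tmm <- theta; tmm[i] <- tmm[i] - hh; tmm[j] <- tmm[j] - hh
    H[i, j] <- H[j, i] <-
      (f_tot(tpp) - f_tot(tpm) - f_tot(tmp) + f_tot(tmm)) / (4 * hh^2)
  }
  A <- -H / n
  AinvB <- tryCatch(solve(A, B), error = function(e)
    stop("observed information matrix is singular; use the ordinary LRT instead",
         call. = FALSE))
  sum(diag(AinvB)) / d
}

#' Scaling correction factor for a fitted model
#'
#' Computes `c = trace(A^-1 B) / d` from the observed average information
#' `A` and the average outer product of per-observation scores `B` (both by
#' numerical differentiation at the ML estimate). With a correctly
#' specified model and large `n`, `c` is close to 1; the factors of two
#' nested fits feed [sb_scaled_difference()].
#'
#' @param model A fitted `lca_model` or `lta_model`.
#' @param ... Method arguments: the fitting data (`x` for LCA; `x1`, `x2`,
#'   `arm` for LTA).
#' @return Scalar scaling correction factor.
#' @export
scaling_correction <- function(model, ...) UseMethod("scaling_correction")

#' @rdname scaling_correction
#' @param x Indicator data used for the fit.
#' @export
scaling_correction.lca_model <- function(model, x, ...) {
  X <- .as_indicator_values(x)
  pat <- .collapse_patterns(X)
  K <- model$K; J <- dim(model$pi)[2]
  theta <- c(.logits1(model$lambda), .pack_pi(model$pi))
  f_vec <- function(th) {
    lambda <- .softmax1(th[seq_len(K - 1)])
    pi <- .unpack_pi(th[-seq_len(K - 1)], K, J)
    if (K == 1) {
      lambda <- 1
      pi <- .unpack_pi(th, K, J)
    }
    log(drop(.pattern_probs(pat$X, pi) %*% lambda))
  }
  if (K == 1) theta <- .pack_pi(model$pi)
  .sandwich_c(f_vec, theta, pat$w, model$n_params)
}

#' @rdname scaling_correction
#' @param x1,x2,arm The fitting data, as in [lta_fit()].
#' @export
scaling_correction.lta_model <- function(model, x1, x2, arm, ...) {
  if (!model$constraints$arm_invariant_measurement)
    stop("scaling correction is implemented for arm-invariant measurement models")
  prep <- .lta_prepare(x1, x2, arm)
  armf <- factor(prep$arm, levels = model$arm_levels)
  K <- model$K; J <- ncol(prep$X1); G <- length(model$arm_levels)
  free <- model$free_classes
  cons <- model$constraints

  pats <- lapply(seq_len(G), function(g) {
    i <- which(armf == model$arm_levels[g])
    .collapse_patterns(cbind(prep$X1[i, , drop = FALSE],
                             prep$X2[i, , drop = FALSE]))
  })
  w <- unlist(lapply(pats, `[[`, "w"))

  n_tau <- if (cons$arm_specific_tau) G else 1
  theta <- c(.logits1(model$delta),
             unlist(lapply(seq_len(n_tau), function(g)
               .pack_rows(model$tau[[g]]))),
             .pack_pi(model$pi_w1),
             if (length(free)) .pack_pi(model$pi_w2[free, , , drop = FALSE]))

  f_vec <- function(th) {
    idx <- 1L
    take <- function(m) {
      out <- th[idx:(idx + m - 1L)]; idx <<- idx + m; out
    }
    delta <- .softmax1(take(K - 1L))
    taus <- lapply(seq_len(n_tau), function(g)
      .unpack_rows(take(K * (K - 1L)), K, K))
    if (!cons$arm_specific_tau) taus <- rep(taus, G)
    pi1 <- .unpack_pi(take(K * J * 2L), K, J)
    pi2 <- pi1
    if (length(free))
      pi2[free, , ] <- .unpack_pi(take(length(free) * J * 2L), length(free), J)
    out <- vector("list", G)
    for (g in seq_len(G)) {
      Xp <- pats[[g]]$X
      A <- .pattern_probs(Xp[, seq_len(J), drop = FALSE], pi1)
      B <- .pattern_probs(Xp[, J + seq_len(J), drop = FALSE], pi2)
      Ad <- A * rep(delta, each = nrow(A))
      out[[g]] <- log(rowSums(Ad * (B %*% t(taus[[g]]))))
    }
    unlist(out)
  }
  .sandwich_c(f_vec, theta, w, model$n_params)
}
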