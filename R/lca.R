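# Latent class analysis for the 3-category risk indicators.
#
# Estimation works on collapsed response patterns: with 7 three-category
# items there are at most 3^7 complete patterns (4^7 with missingness), so
# the per-iteration cost of EM is independent of N once patterns are
# tabulated. Missing entries are handled by dropping the corresponding
# likelihood factors (missing at random).

.PI_FLOOR <- 1e-6

.as_indicator_values <- function(x) {
  v <- if (inherits(x, "indicator_matrix")) x$values
       else if (is.matrix(x)) x
       else stop("expected an indicator_matrix or a matrix of categories")
  if (any(!is.na(v) & !(v %in% 0:2)))
    stop("indicator entries must be 0, 1 or 2 (or NA)")
  v
}

# class-conditional pattern probabilities: P x K matrix of
# prod_j pi[k, j, x_j] over observed j
.pattern_probs <- function(X, pi) {
  P <- nrow(X); K <- dim(pi)[1]
  B <- matrix(1, P, K)
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    obs <- which(!is.na(xj))
    if (!length(obs)) next
    cj <- xj[obs] + 1L
    for (k in seq_len(K))
      B[obs, k] <- B[obs, k] * pi[k, j, ][cj]
  }
  B
}

.normalize_pi <- function(counts) {
  # counts: K x C; floor and renormalize rows
  p <- pmax(counts, 0)
  p <- p / pmax(rowSums(p), .Machine$double.xmin)
  p <- pmax(p, .PI_FLOOR)
  p / rowSums(p)
}

.lca_em_once <- function(X, w, K, lambda, pi, max_iter, tol) {
  J <- ncol(X); C <- 3L
  n <- sum(w)
  # per-item category indicator matrices (missing rows all-zero)
  Ind <- lapply(seq_len(J), function(j) {
    m <- matrix(0, nrow(X), C)
    obs <- which(!is.na(X[, j]))
    m[cbind(obs, X[obs, j] + 1L)] <- 1
    m
  })
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    B <- .pattern_probs(X, pi)
    lik <- drop(B %*% lambda)
    ll <- sum(w * log(lik))
    trace <- c(trace, ll)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    R <- B * rep(lambda, each = nrow(B)) / lik   # P x K responsibilities
    WR <- R * w
    Nk <- colSums(WR)
    lambda <- Nk / n
    for (j in seq_len(J)) {
      cnt <- crossprod(WR, Ind[[j]])             # K x C weighted counts
      pi[, j, ] <- .normalize_pi(cnt)
    }
  }
  list(lambda = lambda, pi = pi, loglik = trace[length(trace)],
       trace = trace, converged = converged, n_iter = length(trace))
}

.random_lca_start <- function(K, J = 7L, C = 3L) {
  lambda <- stats::runif(K, 0.5, 1.5); lambda <- lambda / sum(lambda)
  pi <- array(stats::runif(K * J * C, 0.1, 1), c(K, J, C))
  pi <- pi / rep(apply(pi, c(1, 2), sum), times = C)
  list(lambda = lambda, pi = pi)
}

# canonical class labels: the field's names for the four-profile solution,
# generic otherwise
.class_labels <- function(K) {
  if (K == 4) c("low", "equipment", "moderate", "high")
  else paste0("class", seq_len(K))
}

# canonical risk ordering: ascending composite score of expected
# syringe-sharing (item 1, weight 10) and cooker-sharing (item 2) category
.risk_score <- function(pi) {
  10 * (pi[, 1, ] %*% 0:2) + (pi[, 2, ] %*% 0:2)
}

.risk_order <- function(pi) order(drop(.risk_score(pi)))

#' Fit a latent class model by maximum likelihood
#'
#' EM estimation of a `K`-class model for the 7 three-category indicators,
#' with multiple random starts; the highest-loglikelihood solution is
#' returned. Missing item entries are marginalized out of the likelihood
#' (missing at random). The fitted classes are relabeled into canonical risk
#' order - ascending expected syringe-sharing category, cooker sharing
#' breaking near-ties - so that class 1 is "low risk" and class `K` is
#' "high risk" reproducibly across starts and seeds.
#'
#' @param x An `indicator_matrix` or an N x J integer matrix with entries in
#'   `{0,1,2}` / `NA`.
#' @param K Number of latent classes (>= 1).
#' @param n_starts Number of random EM initializations.
#' @param max_iter Maximum EM iterations per start.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param seed Optional seed for the random starts.
#' @param starts Optional list of explicit starting values (each a list with
#'   `lambda`, `pi`), tried in addition to the random starts.
#' @return An object of class `lca_model`: `K`, `lambda`, `pi`
#'   (`K x J x 3`), `loglik`, `n_params`, `converged`, `n_starts`, `n`,
#'   `trace` (loglik path of the best start) and `start_log` (one entry per
#'   EM start with its final loglik).
#' @export
#' @examples
#' sc <- generate_cohort(default_study_config(n = 300, seed = 2))
#' ind <- recode_cohort(sc$cohort)
#' w1 <- ind$values[ind$wave == "baseline", ]
#' fit <- lca_fit(w1, K = 2, n_starts = 5, seed = 1)
#' fit$lambda
lca_fit <- function(x, K, n_starts = 50, max_iter = 1000, tol = 1e-7,
                    seed = NULL, starts = NULL) {
  X <- .as_indicator_values(x)
  stopifnot(K >= 1, n_starts >= 1 || length(starts) >= 1)
  pat <- .collapse_patterns(X)
  n_pat <- nrow(pat$X)
  if (n_pat < K)
    stop(sprintf("only %d distinct observed patterns; cannot identify K=%d classes",
                 n_pat, K))
  J <- ncol(X)
  d <- (K - 1) + K * J * 2L
  if (d > nrow(X) - 1)
    warning(sprintf("K=%d has %d free parameters for %d observations; model may be unidentified",
                    K, d, nrow(X)))
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  start_log <- data.frame(start = integer(0), loglik = numeric(0),
                          converged = logical(0))
  init_list <- starts %||% list()
  n_random <- max(n_starts - length(init_list), if (length(init_list)) 0 else 1)
  for (s in seq_len(length(init_list) + n_random)) {
    init <- if (s <= length(init_list)) init_list[[s]] else .random_lca_start(K, J)
    fit <- .lca_em_once(pat$X, pat$w, K, init$lambda, init$pi, max_iter, tol)
    start_log <- rbind(start_log,
                       data.frame(start = s, loglik = fit$loglik,
                                  converged = fit$converged))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!any(start_log$converged))
    stop("no EM start converged within max_iter; best loglik trace attached",
         call. = FALSE)

  ord <- .risk_order(best$pi)
  model <- structure(list(
    K = as.integer(K),
    lambda = best$lambda[ord],
    pi = best$pi[ord, , , drop = FALSE],
    loglik = best$loglik,
    n_params = d,
    converged = best$converged,
    n_starts = nrow(start_log),
    n = nrow(X),
    n_patterns = n_pat,
    trace = best$trace,
    start_log = start_log,
    item_names = colnames(X) %||% lta_items()$name[seq_len(J)]
  ), class = "lca_model")
  names(model$lambda) <- .class_labels(K)
  dimnames(model$pi) <- list(.class_labels(K), model$item_names,
                             c("c0", "c1", "c2"))
  model
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf("<lca_model> K=%d, N=%d, loglik=%.3f, params=%d, converged=%s\n",
              x$K, x$n, x$loglik, x$n_params, x$converged))
  cat("class proportions:", paste(sprintf("%.3f", x$lambda), collapse = " "), "\n")
  invisible(x)
}

#' Posterior class-membership probabilities
#'
#' Computes `p_ik` proportional to `lambda_k * prod_j pi[k, j, x_ij]` over
#' the non-missing items of each row, normalized. A row with all items
#' missing carries no information and gets a uniform posterior (with a
#' warning). Modal assignments break ties by the lowest class index.
#'
#' @param model An `lca_model`.
#' @param x Indicator data with the same item structure as the fit.
#' @return An object of class `lca_posterior`: `p` (N x K), `modal`
#'   (integer), `K`.
#' @export
posterior_probs <- function(model, x) {
  X <- .as_indicator_values(x)
  if (ncol(X) != dim(model$pi)[2])
    stop("data and model have different numbers of items")
  B <- .pattern_probs(X, model$pi)
  num <- B * rep(model$lambda, each = nrow(B))
  p <- num / rowSums(num)
  empty <- rowSums(!is.na(X)) == 0
  if (any(empty)) {
    p[empty, ] <- 1 / model$K
    warning(sprintf("%d row(s) with all items missing: uniform posterior assigned",
                    sum(empty)))
  }
  modal <- max.col(p, ties.method = "first")
  structure(list(p = p, modal = modal, K = model$K), class = "lca_posterior")
}

#' Classification entropy of a posterior matrix
#'
#' Relative entropy `E = 1 - sum_i sum_k (-p_ik log p_ik) / (N log K)`,
#' with `0 log 0 := 0`. `E = 1` means perfect class separation and `E = 0`
#' uniform (uninformative) posteriors. With `K = 1` classification is
#' degenerate and `E` is defined as 1, with a warning.
#'
#' @param posterior An `lca_posterior` or an N x K probability matrix.
#' @param K Number of classes (taken from the posterior if omitted).
#' @return Scalar in `[0, 1]`.
#' @export
classification_entropy <- function(posterior, K = NULL) {
  p <- if (inherits(posterior, "lca_posterior")) posterior$p else as.matrix(posterior)
  K <- K %||% ncol(p)
  if (K == 1) {
    warning("entropy is degenerate for K=1; returning 1")
    return(1)
  }
  plogp <- ifelse(p > 0, p * log(p), 0)
  1 - sum(-plogp) / (nrow(p) * log(K))
}

#' Average posterior probabilities by most likely class
#'
#' Entry `(a, b)` is the mean posterior probability of class `b` among rows
#' whose modal class is `a`; the diagonal is the usual classification
#' quality diagnostic. Rows sum to 1. An empty modal class yields a row of
#' `NaN` with a warning.
#'
#' @param posterior An `lca_posterior`.
#' @return K x K matrix.
#' @export
classification_table <- function(posterior) {
  stopifnot(inherits(posterior, "lca_posterior"))
  K <- posterior$K
  out <- matrix(NaN, K, K)
  for (a in seq_len(K)) {
    i <- posterior$modal == a
    if (!any(i)) {
      warning(sprintf("no rows modally assigned to class %d", a))
      next
    }
    out[a, ] <- colMeans(posterior$p[i, , drop = FALSE])
  }
  out
}

#' Fit indices for a latent class model
#'
#' @param model An `lca_model`.
#' @param posterior Optional precomputed `lca_posterior` for the fitting
#'   data (required for the entropy and average-posterior diagnostics).
#' @return A one-row data.frame: `K`, `loglik`, `n_params`, `AIC`
#'   (`-2L + 2d`), `BIC` (`-2L + d log N`), `aBIC` (sample-size-adjusted
#'   BIC with `n* = (N + 2) / 24`), `entropy`, `min_avg_post` and
#'   `max_avg_post` (range of the classification-table diagonal).
#' @export
fit_indices <- function(model, posterior = NULL) {
  d <- model$n_params; L <- model$loglik; N <- model$n
  ent <- NA_real_; lo <- NA_real_; hi <- NA_real_
  if (!is.null(posterior)) {
    ent <- if (model$K == 1) 1 else classification_entropy(posterior)
    diagc <- diag(classification_table(posterior))
    lo <- min(diagc, na.rm = TRUE); hi <- max(diagc, na.rm = TRUE)
  }
  data.frame(K = model$K, loglik = L, n_params = d,
             AIC = -2 * L + 2 * d,
             BIC = -2 * L + d * log(N),
             aBIC = -2 * L + d * log((N + 2) / 24),
             entropy = ent, min_avg_post = lo, max_avg_post = hi)
}

#' Fit and tabulate latent class models over a range of K
#'
#' Fits each class count in `K_range` and reports one row of fit indices
#' per model. No automatic choice is made: class enumeration combines the
#' indices with substantive judgment, so the table is the output.
#'
#' @param x Indicator data (see [lca_fit()]).
#' @param K_range Integer vector of class counts (default 2:6).
#' @param ... Passed to [lca_fit()] (`n_starts`, `tol`, ...).
#' @param seed Optional master seed; start seeds are derived per K.
#' @return A data.frame with one row per K (class `lca_selection`), with the
#'   fitted models in `attr(, "models")`.
#' @export
select_models <- function(x, K_range = 2:6, seed = NULL, ...) {
  stopifnot(length(K_range) >= 1, all(K_range >= 1))
  models <- list()
  rows <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    s <- if (is.null(seed)) NULL else derive_seed(seed, paste0("lca_K", K))
    m <- lca_fit(x, K = K, seed = s, ...)
    post <- posterior_probs(m, x)
    rows[[i]] <- fit_indices(m, post)
    models[[as.character(K)]] <- m
  }
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  class(out) <- c("lca_selection", "data.frame")
  out
}

#' Simulate indicator data from a fitted latent class model
#'
#' @param model An `lca_model`.
#' @param n Number of rows.
#' @param seed Optional seed.
#' @return List with `x` (n x J category matrix) and `class` (true classes).
#' @export
simulate_lca <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- sample.int(model$K, n, replace = TRUE, prob = model$lambda)
  J <- dim(model$pi)[2]
  x <- matrix(NA_integer_, n, J)
  for (j in seq_len(J)) {
    pm <- model$pi[cls, j, , drop = TRUE]
    if (n == 1L) pm <- matrix(pm, 1L)
    x[, j] <- .draw_rows(pm) - 1L
  }
  list(x = x, class = cls)
}

#' Bootstrap likelihood ratio test for K versus K-1 classes
#'
#' Parametric bootstrap: the (K-1)-class model is fit to the data, `n_boot`
#' datasets of the same size are simulated from it, both models are refit on
#' each (warm-started from the parent fits plus random starts), and the
#' p-value is `(1 + #{boot -2*dLL >= observed}) / (n_kept + 1)`. Bootstrap
#' replicates whose refits fail to converge are dropped and counted, with a
#' warning if more than 5% are lost.
#'
#' @param x Indicator data.
#' @param K Number of classes under the alternative (>= 2).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Optional seed.
#' @param n_starts Random starts for the two fits on the observed data.
#' @param n_starts_boot Starts per bootstrap refit (warm start counts as
#'   one).
#' @param max_iter,tol Passed to the EM.
#' @return List of class `blrt_result`: `statistic` (observed `-2 dLL`),
#'   `p_value`, `boot_stats`, `n_dropped`, and the two fitted models.
#' @export
blrt <- function(x, K, n_boot = 100, seed = NULL, n_starts = 20,
                 n_starts_boot = 2, max_iter = 1000, tol = 1e-7) {
  if (K < 2) stop("K must be >= 2 for the bootstrap likelihood ratio test")
  if (n_boot < 1) stop("n_boot must be >= 1")
  X <- .as_indicator_values(x)
  if (!is.null(seed)) set.seed(seed)
  fit0 <- lca_fit(X, K - 1, n_starts = n_starts, max_iter = max_iter, tol = tol)
  fit1 <- lca_fit(X, K, n_starts = n_starts, max_iter = max_iter, tol = tol)
  obs <- 2 * (fit1$loglik - fit0$loglik)
  n <- nrow(X)
  stats_b <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    sim <- simulate_lca(fit0, n)$x
    f0 <- try(lca_fit(sim, K - 1, n_starts = n_starts_boot,
                      max_iter = max_iter, tol = tol,
                      starts = list(list(lambda = fit0$lambda, pi = fit0$pi))),
              silent = TRUE)
    f1 <- try(lca_fit(sim, K, n_starts = n_starts_boot,
                      max_iter = max_iter, tol = tol,
                      starts = list(list(lambda = fit1$lambda, pi = fit1$pi))),
              silent = TRUE)
    if (inherits(f0, "try-error") || inherits(f1, "try-error")) next
    stats_b[b] <- 2 * (f1$loglik - f0$loglik)
  }
  kept <- stats_b[!is.na(stats_b)]
  n_dropped <- n_boot - length(kept)
  if (n_dropped > 0.05 * n_boot)
    warning(sprintf("%d of %d bootstrap replicates dropped (non-convergence)",
                    n_dropped, n_boot))
  p <- (1 + sum(kept >= obs)) / (length(kept) + 1)
  structure(list(statistic = obs, p_value = p, boot_stats = kept,
                 n_boot = n_boot, n_dropped = n_dropped,
                 fit_null = fit0, fit_alt = fit1),
            class = "blrt_result")
}

#' @export
print.blrt_result <- function(x, ...) {
  cat(sprintf("Bootstrap LRT: -2dLL = %.3f, p = %.4g (%d replicates, %d dropped)\n",
              x$statistic, x$p_value, x$n_boot - x$n_dropped, x$n_dropped))
  invisible(x)
}
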