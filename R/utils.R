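#' Derive a deterministic child seed from a master seed
#'
#' Every stochastic stage of the pipeline receives its own seed derived from
#' the master seed and a stage label, so that changing the master seed changes
#' all stochastic draws while re-running with the same master seed reproduces
#' them exactly, and so that adding a stage never perturbs the seeds of the
#' others.
#'
#' @param master Integer master seed.
#' @param label Character stage label, e.g. `"simulate"` or `"lca_w1"`.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "simulate")
#' derive_seed(1L, "simulate") == derive_seed(1L, "simulate")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(label), length(label) == 1L, nzchar(label))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master) %% m
  for (code in utf8ToInt(label)) {
    # polynomial rolling hash; products stay below 2^53 so doubles are exact
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# --- internal helpers ---------------------------------------------------

#' @noRd
.check_prob_vec <- function(p, what, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < -tol))
    stop(sprintf("%s must be a vector of non-negative probabilities", what))
  if (abs(sum(p) - 1) > 1e-8)
    stop(sprintf("%s must sum to 1 (got %.10f)", what, sum(p)))
  invisible(TRUE)
}

#' Draw one categorical value per row of a probability matrix
#' @noRd
.draw_rows <- function(pmat) {
  # pmat: n x C, rows sum to 1; returns integer in 1..C per row
  cs <- pmat %*% upper.tri(diag(ncol(pmat)), diag = TRUE)
  u <- stats::runif(nrow(pmat))
  as.integer(rowSums(u > cs) + 1L)
}

#' Collapse rows of an indicator matrix into unique patterns with weights
#' @noRd
.collapse_patterns <- function(X, extra = NULL) {
  key <- do.call(paste, c(lapply(seq_len(ncol(X)), function(j) X[, j]),
                          as.list(extra %||% list()), list(sep = "\r")))
  grp <- match(key, unique(key))
  keep <- !duplicated(grp)
  list(X = X[keep, , drop = FALSE],
       w = as.double(tabulate(grp)),
       map = grp,
       keep = which(keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
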