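#' Configuration for the full analysis pipeline
#'
#' @param generator An `lta_config` for synthetic input, or `NULL` to read
#'   an existing cohort from `cohort_path`.
#' @param cohort_path CSV path of a raw cohort (ignored when `generator` is
#'   given).
#' @param K_range Class counts for the per-wave enumeration stage.
#' @param K Class count for the transition model.
#' @param n_starts,tol,max_iter EM control for all fits.
#' @param covariate_names Adjustment covariates for the effects stage
#'   (columns of the cohort file), or `NULL` for the unadjusted model.
#' @param complete_case If `TRUE`, restrict the transition and effects
#'   stages to participants observed at both waves (the sensitivity
#'   analysis); default `FALSE` retains wave-2-missing participants by
#'   marginalization.
#' @param compare_arm_measurement Also fit the model with measurement free
#'   across arms and report the invariance comparison (default `TRUE`).
#' @param compare_time_measurement Also fit the model with wave-2
#'   measurement free and report the time-invariance comparison (default
#'   `TRUE`).
#' @param seed Master seed; every stochastic stage derives its own child
#'   seed from it (see [derive_seed()]).
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, cohort_path = NULL,
                            K_range = 3:5, K = 4, n_starts = 20,
                            tol = 1e-7, max_iter = 1000,
                            covariate_names = NULL, complete_case = FALSE,
                            compare_arm_measurement = TRUE,
                            compare_time_measurement = TRUE,
                            seed = NULL, out_dir = NULL) {
  if (is.null(seed)) stop("a master seed is mandatory: the pipeline has stochastic stages")
  if (is.null(generator) && is.null(cohort_path))
    stop("either a generator config or a cohort path is required")
  structure(list(generator = generator, cohort_path = cohort_path,
                 K_range = K_range, K = as.integer(K), n_starts = n_starts,
                 tol = tol, max_iter = max_iter,
                 covariate_names = covariate_names,
                 complete_case = isTRUE(complete_case),
                 compare_arm_measurement = isTRUE(compare_arm_measurement),
                 compare_time_measurement = isTRUE(compare_time_measurement),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.plog <- function(log_lines, stage, msg) {
  c(log_lines, sprintf("[%s] %s", stage, msg))
}

#' Align a long cohort into row-matched two-wave indicator matrices
#'
#' @param ind An `indicator_matrix` from [recode_cohort()].
#' @return List with `x1`, `x2` (row-aligned matrices; `x2` rows all-`NA`
#'   for participants without a follow-up record), `arm`, `id`,
#'   `has_followup`.
#' @export
align_waves <- function(ind) {
  stopifnot(inherits(ind, "indicator_matrix"))
  b <- which(ind$wave == "baseline")
  f <- which(ind$wave %in% c("m3", "m6"))
  id_b <- ind$participant_id[b]
  x1 <- ind$values[b, , drop = FALSE]
  x2 <- matrix(NA_integer_, length(b), ncol(x1),
               dimnames = dimnames(x1))
  m <- match(ind$participant_id[f], id_b)
  x2[m[!is.na(m)], ] <- ind$values[f[!is.na(m)], , drop = FALSE]
  list(x1 = x1, x2 = x2, arm = ind$arm[b], id = id_b,
       has_followup = rowSums(!is.na(x2)) > 0)
}

#' Run the full latent-transition analysis pipeline
#'
#' Executes the stages in the analysis order: (1) simulate or read the
#' cohort; (2) recode raw items to 3-category indicators; (3) per-wave
#' latent class enumeration over `K_range` with fit indices; (4) the
#' two-wave latent transition model with arm-specific transitions, plus the
#' time- and arm-invariance comparison fits and their likelihood-ratio
#' tests; (5) the effects stage: arm-by-baseline-class logit, average
#' marginal effects and odds ratios per class, attrition and
#' trial-participation chi-square tests. Every stochastic stage is seeded
#' deterministically from the master seed, and all outputs embed the config
#' hash and seed so a re-run reproduces every number.
#'
#' @param config A [pipeline_config()].
#' @return A report list (invisibly written to `out_dir` as JSON/CSV when
#'   requested) with elements `selection`, `lta`, `invariance`, `effects`,
#'   `provenance`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  logl <- character(0)
  seed <- config$seed

  # --- stage 1: input ----------------------------------------------------
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- derive_seed(seed, "simulate")
    sc <- generate_cohort(gen)
    cohort <- sc$cohort
    truth <- sc$truth
    logl <- .plog(logl, "simulate",
                  sprintf("generated cohort n=%d with seed %d", gen$n, gen$seed))
  } else {
    cohort <- read_cohort(config$cohort_path)
    truth <- NULL
    logl <- .plog(logl, "input", sprintf("read %d assessment rows", nrow(cohort)))
  }

  # --- stage 2: recoding (deterministic; unaffected by the seed) ---------
  ind <- recode_cohort(cohort)
  aligned <- align_waves(ind)
  logl <- .plog(logl, "recode",
                sprintf("%d participants, %d with follow-up",
                        length(aligned$id), sum(aligned$has_followup)))

  randomized_ids <- cohort$participant_id[cohort$wave == "baseline" &
                                            cohort$arm != "none"]
  trial <- aligned$id %in% randomized_ids
  keep <- trial & if (config$complete_case) aligned$has_followup else TRUE
  x1 <- aligned$x1[keep, , drop = FALSE]
  x2 <- aligned$x2[keep, , drop = FALSE]
  arm <- droplevels(factor(aligned$arm[keep]))

  # --- stage 3: per-wave class enumeration -------------------------------
  selection <- list()
  for (wv in c("wave1", "wave2")) {
    xw <- if (wv == "wave1") aligned$x1 else {
      aligned$x2[rowSums(!is.na(aligned$x2)) > 0, , drop = FALSE]
    }
    sel <- select_models(xw, K_range = config$K_range,
                         seed = derive_seed(seed, paste0("lca_", wv)),
                         n_starts = config$n_starts, tol = config$tol,
                         max_iter = config$max_iter)
    for (m in attr(sel, "models"))
      for (s in seq_len(nrow(m$start_log)))
        logl <- .plog(logl, paste0("lca_", wv),
                      sprintf("K=%d start %d loglik %.4f", m$K,
                              m$start_log$start[s], m$start_log$loglik[s]))
    selection[[wv]] <- sel
  }

  # --- stage 4: latent transition model ----------------------------------
  fit_main <- lta_fit(x1, x2, arm, K = config$K,
                      constraints = lta_constraints(),
                      n_starts = config$n_starts, tol = config$tol,
                      max_iter = config$max_iter,
                      seed = derive_seed(seed, "lta_main"))
  for (s in seq_len(nrow(fit_main$start_log)))
    logl <- .plog(logl, "lta_main",
                  sprintf("start %d loglik %.4f", s, fit_main$start_log$loglik[s]))
  invariance <- list()
  if (config$compare_time_measurement) {
    fit_free_t <- lta_fit(x1, x2, arm, K = config$K,
                          constraints = lta_constraints(time_invariant = FALSE),
                          n_starts = config$n_starts, tol = config$tol,
                          max_iter = config$max_iter, warm_from = fit_main,
                          seed = derive_seed(seed, "lta_free_time"))
    invariance$time <- list(restricted = fit_main$loglik,
                            general = fit_free_t$loglik,
                            test = lrt_compare(fit_main, fit_free_t))
    logl <- .plog(logl, "lta_free_time",
                  sprintf("loglik %.4f", fit_free_t$loglik))
  }
  if (config$compare_arm_measurement) {
    fit_free_a <- lta_fit(x1, x2, arm, K = config$K,
                          constraints = lta_constraints(
                            arm_invariant_measurement = FALSE),
                          n_starts = config$n_starts, tol = config$tol,
                          max_iter = config$max_iter, warm_from = fit_main,
                          seed = derive_seed(seed, "lta_free_arm"))
    invariance$arm <- list(restricted = fit_main$loglik,
                           general = fit_free_a$loglik,
                           test = lrt_compare(fit_main, fit_free_a))
    logl <- .plog(logl, "lta_free_arm",
                  sprintf("loglik %.4f", fit_free_a$loglik))
  }

  # --- stage 5: effects --------------------------------------------------
  post <- lta_posterior(fit_main, x1, x2, arm)
  has_f <- rowSums(!is.na(x2)) > 0
  outcome <- ifelse(has_f, as.integer(post$modal_w2 == 1L), NA_integer_)
  covars <- NULL
  if (!is.null(config$covariate_names)) {
    base_rows <- cohort[cohort$wave == "baseline", , drop = FALSE]
    base_rows <- base_rows[match(aligned$id[keep], base_rows$participant_id), ,
                           drop = FALSE]
    covars <- base_rows[config$covariate_names]
  }
  glm_fit <- lowrisk_glm(outcome, arm, post$modal_w1, covariates = covars)
  ame <- average_marginal_effects(glm_fit)
  ors <- arm_odds_ratios(glm_fit)
  high <- as.character(config$K)
  attr_t <- tryCatch(
    attrition_test(has_f[post$modal_w1 == config$K],
                   arm[post$modal_w1 == config$K]),
    error = function(e) e$message)

  part_t <- NULL
  if (any(!trial)) {
    w1_lca <- attr(selection$wave1, "models")[[as.character(config$K)]]
    if (!is.null(w1_lca)) {
      p_all <- posterior_probs(w1_lca, aligned$x1)
      part_t <- tryCatch(participation_bias_test(p_all$modal, trial),
                         error = function(e) e$message)
    }
  }
  logl <- .plog(logl, "effects",
                sprintf("logit n=%d; AME(high)=%.4f", glm_fit$n,
                        ame$dydx[ame$class == high]))

  provenance <- list(seed = seed,
                     child_seeds = list(
                       simulate = if (is.null(config$generator)) NULL
                                  else derive_seed(seed, "simulate"),
                       lta_main = derive_seed(seed, "lta_main")),
                     package_version = as.character(utils::packageVersion("ltarisk")))

  report <- list(
    selection = selection,
    lta = list(delta = fit_main$delta, tau = fit_main$tau,
               marginal = marginal_class_probs(fit_main),
               loglik = fit_main$loglik, n_params = fit_main$n_params),
    invariance = invariance,
    effects = list(ame = ame, odds_ratios = ors, attrition = attr_t,
                   participation = part_t,
                   complete_case = config$complete_case),
    provenance = provenance,
    log = logl,
    fit_main = fit_main,
    truth = truth)

  if (!is.null(config$out_dir)) .write_report(report, config, cohort, ind)
  invisible(report)
}

.write_report <- function(report, config, cohort, ind) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  cfg_json <- file.path(od, "config.json")
  cfg_out <- config
  cfg_out$generator <- if (is.null(config$generator)) NULL else
    lapply(config$generator, function(v) if (is.function(v)) NULL else v)
  jsonlite::write_json(cfg_out, cfg_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))
  utils::write.csv(cohort, file.path(od, "cohort.csv"), row.names = FALSE,
                   na = "")
  write_indicators(ind, file.path(od, "indicators.csv"))
  sel_tab <- do.call(rbind, lapply(names(report$selection), function(wv) {
    s <- report$selection[[wv]]
    attr(s, "models") <- NULL
    cbind(wave = wv, as.data.frame(s))
  }))
  utils::write.csv(sel_tab, file.path(od, "lca_selection.csv"),
                   row.names = FALSE)
  out <- list(config_hash = cfg_hash, seed = config$seed,
              lta = report$lta,
              invariance = lapply(report$invariance, function(v)
                list(restricted = v$restricted, general = v$general,
                     statistic = v$test$statistic, df = v$test$df,
                     p_value = v$test$p_value)),
              effects = report$effects,
              log = report$log)
  jsonlite::write_json(out, file.path(od, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(od)
}
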