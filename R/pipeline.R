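#' Configuration bundle for the full analysis pipeline
#'
#' @param seed master seed; stage seeds (imputation, per-arm samplers)
#'   are derived from it so one integer reproduces the whole run.
#' @param screen_threshold missingness screening threshold (default the
#'   <50% acceptability rule).
#' @param impute an [impute_config()] (its seed is overridden by the
#'   derived stage seed).
#' @param bma a [bma_config()] (same).
#' @param selection_rule predictor-selection rule, see
#'   [select_predictors()].
#' @param pai_threshold clinically meaningful PAI threshold (PHQ-9
#'   points, default 5).
#' @param clip_predictions clip factual/counterfactual predictions to
#'   the 0-27 outcome scale before computing PAIs (default FALSE: raw
#'   linear predictors).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, screen_threshold = 0.5,
                            impute = impute_config(), bma = bma_config(),
                            selection_rule = "highest_posterior_model",
                            pai_threshold = 5, clip_predictions = FALSE) {
  structure(list(seed = as.integer(seed), screen_threshold = screen_threshold,
                 impute = impute, bma = bma,
                 selection_rule = selection_rule,
                 pai_threshold = pai_threshold,
                 clip_predictions = isTRUE(clip_predictions)),
            class = "pipeline_config")
}

subset_coded <- function(coded, rows) {
  structure(list(x = coded$x[rows, , drop = FALSE], meta = coded$meta,
                 patient_id = coded$patient_id[rows],
                 arm = coded$arm[rows], outcome = coded$outcome[rows]),
            class = "coded_matrix")
}

#' Run the full treatment-allocation analysis
#'
#' Orchestrates the whole pipeline on a patient-level trial table:
#' completer filtering, missingness screening, iterative random-forest
#' imputation, design encoding, per-arm Bayesian model averaging
#' (exhaustive enumeration when the design is small enough, the
#' MCMC + sampling-without-replacement scheme otherwise), predictor
#' selection, leave-one-out factual/counterfactual prediction and the
#' PAI cohort summary. All intermediate artifacts, the configuration
#' echo and the final report are written under `outdir`; the report JSON
#' is fully determined by the input table and the master seed.
#'
#' @param table trial table (e.g. from [generate_trial()] or
#'   [read_trial()]).
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if needed); `NULL` skips all
#'   file output.
#' @return (invisibly) list with the completer report, dropped
#'   covariates, imputation diagnostics, per-arm `bma_result`s, selected
#'   predictors, per-patient predictions, `pai_summary` and the report
#'   list written to `report.json`.
#' @export
run_pipeline <- function(table, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outdir))
        writeLines(c(log_lines, sprintf("ABORTED at stage %s: %s", name,
                                        conditionMessage(e))),
                   file.path(outdir, "log.txt"))
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  seeds <- derive_seeds(config$seed, 3L)
  note("master seed %d; stage seeds: impute %d, bma TAU %d, bma BLEND %d",
       config$seed, seeds[1], seeds[2], seeds[3])

  fc <- stage("filter_completers", filter_completers(table))
  note("completer filter: removed %d, retained %d (TAU %d, BLEND %d)",
       fc$report$removed, fc$report$retained,
       fc$report$retained_tau, fc$report$retained_blend)

  sm <- stage("screen_missingness",
              screen_missingness(fc$table, config$screen_threshold))
  note("missingness screen (threshold %.2f): dropped %d covariate(s)%s",
       config$screen_threshold, length(sm$dropped),
       if (length(sm$dropped)) paste0(": ", paste(names(sm$dropped), collapse = ", ")) else "")

  imp_cfg <- config$impute; imp_cfg$seed <- seeds[1]
  imp <- stage("missforest_impute", missforest_impute(sm$table, imp_cfg))
  note("imputation: %d iteration(s), converged = %s",
       imp$diagnostics$iterations, imp$diagnostics$converged)

  coded <- stage("encode", encode(imp$table))
  p <- ncol(coded$x)
  note("encoded design: %d columns from %d covariates", p,
       length(unique(coded$meta$source)))

  arms <- list(TAU = subset_coded(coded, coded$arm == "TAU"),
               BLEND = subset_coded(coded, coded$arm == "BLEND"))
  bma_fits <- list()
  for (a in names(arms)) {
    cfg <- config$bma
    cfg$seed <- if (a == "TAU") seeds[2] else seeds[3]
    bma_fits[[a]] <- stage(paste0("bma_", a), {
      if (p <= cfg$enumeration_limit) enumerate_models(arms[[a]], config = cfg, arm = a)
      else mcmc_bas(arms[[a]], config = cfg, arm = a)
    })
    note("BMA %s: %s over %d models, top model has %d variables (post prob %.4f)",
         a, bma_fits[[a]]$method, bma_fits[[a]]$n_models_evaluated,
         bma_fits[[a]]$p_gamma[1], bma_fits[[a]]$posterior_prob[1])
  }

  selected <- lapply(bma_fits, select_predictors, rule = config$selection_rule)
  for (a in names(selected))
    note("selected predictors (%s, %s): %s", a, config$selection_rule,
         if (length(selected[[a]])) paste(selected[[a]], collapse = ", ") else "(intercept only)")

  preds <- stage("loo_predictions", rbind(
    loo_predictions(arms$TAU, arms$BLEND, selected$TAU, selected$BLEND),
    loo_predictions(arms$BLEND, arms$TAU, selected$BLEND, selected$TAU)
  ))
  preds <- preds[match(coded$patient_id, preds$patient_id), , drop = FALSE]
  rownames(preds) <- NULL
  if (config$clip_predictions) {
    preds$factual_pred <- pmin(27, pmax(0, preds$factual_pred))
    preds$counterfactual_pred <- pmin(27, pmax(0, preds$counterfactual_pred))
    preds$pai <- abs(preds$factual_pred - preds$counterfactual_pred)
    preds$received_optimal <- preds$factual_pred <= preds$counterfactual_pred
    preds$optimal_arm <- ifelse(preds$received_optimal, preds$received_arm,
                                ifelse(preds$received_arm == "TAU", "BLEND", "TAU"))
  }

  summary <- stage("summarize_pai", summarize_pai(preds, config$pai_threshold))
  hist_breaks <- 0:max(1, ceiling(max(preds$pai)))
  hist_counts <- as.integer(table(cut(preds$pai, breaks = c(hist_breaks, Inf),
                                      right = FALSE)))

  report <- list(
    config = list(seed = config$seed, screen_threshold = config$screen_threshold,
                  selection_rule = config$selection_rule,
                  pai_threshold = config$pai_threshold,
                  clip_predictions = config$clip_predictions,
                  bma = unclass(config$bma), impute = unclass(imp_cfg)),
    completers = fc$report,
    dropped_covariates = as.list(sm$dropped),
    imputation = imp$diagnostics,
    top_models = lapply(bma_fits, top_model_table),
    pip = lapply(bma_fits, function(b) as.list(b$pip)),
    selected_predictors = lapply(selected, as.character),
    pai_histogram = list(breaks = c(hist_breaks, Inf), counts = hist_counts),
    summary = unclass(summary)
  )

  if (!is.null(outdir)) {
    write_json_stable(report, file.path(outdir, "report.json"))
    utils::write.csv(preds, file.path(outdir, "pai_predictions.csv"), row.names = FALSE)
    for (a in names(bma_fits))
      utils::write.csv(top_model_table(bma_fits[[a]]),
                       file.path(outdir, sprintf("top_models_%s.csv", a)),
                       row.names = FALSE)
    pip_df <- data.frame(column = names(bma_fits$TAU$pip),
                         pip_tau = unname(bma_fits$TAU$pip),
                         pip_blend = unname(bma_fits$BLEND$pip))
    utils::write.csv(pip_df, file.path(outdir, "pip.csv"), row.names = FALSE)
    writeLines(log_lines, file.path(outdir, "log.txt"))
  }

  invisible(list(completers = fc$report, dropped = sm$dropped,
                 imputation = imp$diagnostics, bma = bma_fits,
                 selected = selected, predictions = preds,
                 summary = summary, report = report))
}
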