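#' Configuration for iterative random-forest imputation
#'
#' @param max_iterations maximum number of sweeps over the incomplete
#'   variables (default 10; the stopping rule normally fires earlier).
#' @param n_trees trees per random forest (default 100, the algorithm's
#'   canonical default).
#' @param seed integer seed governing every forest fit.
#' @param variable_order `"ascending_missingness"` (default: impute the
#'   least incomplete variable first, as in the canonical algorithm) or
#'   `"as_given"`.
#' @param use_arm include the treatment-arm label as a predictor feature
#'   (the baseline set is imputed pooled across arms by default).
#' @return object of class `impute_config`.
#' @export
impute_config <- function(max_iterations = 10L, n_trees = 100L, seed = 1L,
                          variable_order = c("ascending_missingness", "as_given"),
                          use_arm = TRUE) {
  stopifnot(max_iterations >= 1, n_trees >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 variable_order = match.arg(variable_order),
                 use_arm = isTRUE(use_arm)),
            class = "impute_config")
}

#' Iterative random-forest imputation of baseline covariates
#'
#' Fills missing covariate cells with the iterative random-forest scheme:
#' missing entries are initialized with the column mean (continuous/count)
#' or mode (categorical); then, cycling over the incomplete variables in
#' ascending order of missingness, each variable is regressed (random
#' forest) on all other covariates using its originally observed rows and
#' its originally missing cells are replaced by the forest predictions.
#' Sweeps repeat until the difference between successive imputed matrices
#' *increases* for both the continuous part (normalized squared
#' difference) and the categorical part (disagreement proportion), at
#' which point the previous iterate is returned; or until
#' `max_iterations`.
#'
#' Only baseline covariates are imputed; the outcome column is never part
#' of the model set (outcome missingness is handled by
#' [filter_completers()]). Observed cells are never altered. Imputed
#' categorical values are always levels observed in the data; imputed
#' count values are continuous forest predictions (not rounded).
#'
#' @param table trial table (typically the completer-filtered cohort).
#' @param config an [impute_config()].
#' @return list with `table` (all covariate cells filled) and
#'   `diagnostics` (iterations run, difference trajectories, convergence
#'   flag).
#' @export
missforest_impute <- function(table, config = impute_config()) {
  validate_trial(table)
  stopifnot(inherits(config, "impute_config"))
  covs <- trial_covariate_names(table)
  x <- table[covs]
  for (v in covs) if (is.character(x[[v]])) x[[v]] <- factor(x[[v]])

  n_miss <- vapply(covs, function(v) sum(is.na(x[[v]])), 0L)
  if (all(n_miss == 0L))
    return(list(table = table,
                diagnostics = list(iterations = 0L, diff_continuous = numeric(0),
                                   diff_categorical = numeric(0), converged = TRUE)))
  all_na <- covs[vapply(covs, function(v) all(is.na(x[[v]])), TRUE)]
  if (length(all_na))
    stop("covariate(s) with no observed values: ", paste(all_na, collapse = ", "),
         call. = FALSE)

  is_cat <- vapply(x, is.factor, TRUE)
  na_idx <- lapply(x, function(col) which(is.na(col)))

  # constant observed columns carry no signal for a forest: fill directly
  constant <- vapply(covs, function(v) {
    obs <- x[[v]][!is.na(x[[v]])]
    length(unique(obs)) == 1L
  }, TRUE)
  for (v in covs[constant & n_miss > 0L]) {
    obs1 <- x[[v]][!is.na(x[[v]])][1L]
    x[[v]][na_idx[[v]]] <- obs1
    warning(sprintf("covariate '%s' observed as constant; imputed with that constant", v))
  }

  # mean/mode initialization for everything still missing
  for (v in covs) {
    idx <- na_idx[[v]]
    if (!length(idx) || constant[[v]]) next
    if (is_cat[[v]]) x[[v]][idx] <- stat_mode(x[[v]])
    else x[[v]][idx] <- mean(x[[v]], na.rm = TRUE)
  }

  targets <- covs[n_miss > 0L & !constant]
  if (!length(targets)) {
    table[covs] <- x
    return(list(table = table,
                diagnostics = list(iterations = 0L, diff_continuous = numeric(0),
                                   diff_categorical = numeric(0), converged = TRUE)))
  }
  if (config$variable_order == "ascending_missingness")
    targets <- targets[order(n_miss[targets])]

  preds <- x
  if (config$use_arm) preds$arm <- factor(as.character(table$arm))

  cont_targets <- targets[!is_cat[targets]]
  cat_targets <- targets[is_cat[targets]]
  n_cat_cells <- sum(n_miss[cat_targets])

  set.seed(config$seed)
  diff_cont <- numeric(0); diff_cat <- numeric(0)
  best <- x
  prev_cont <- Inf; prev_cat <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    x_old <- x
    for (v in targets) {
      idx <- na_idx[[v]]
      obs <- setdiff(seq_len(nrow(x)), idx)
      dat <- preds
      dat[[".response."]] <- x[[v]]
      fit <- ranger::ranger(
        dependent.variable.name = ".response.",
        data = dat[obs, c(setdiff(names(preds), v), ".response."), drop = FALSE],
        num.trees = config$n_trees, num.threads = 1L,
        seed = sample.int(.Machine$integer.max - 1L, 1L),
        verbose = FALSE)
      pr <- stats::predict(fit, data = dat[idx, setdiff(names(preds), v), drop = FALSE],
                           num.threads = 1L)$predictions
      x[[v]][idx] <- pr
      preds[[v]] <- x[[v]]
    }
    dc <- if (length(cont_targets)) {
      num_new <- unlist(lapply(cont_targets, function(v) as.numeric(x[[v]])))
      num_old <- unlist(lapply(cont_targets, function(v) as.numeric(x_old[[v]])))
      sum((num_new - num_old)^2) / sum(num_new^2)
    } else NA_real_
    dk <- if (n_cat_cells > 0L) {
      sum(vapply(cat_targets, function(v)
        sum(x[[v]][na_idx[[v]]] != x_old[[v]][na_idx[[v]]]), 0L)) / n_cat_cells
    } else NA_real_
    diff_cont <- c(diff_cont, dc); diff_cat <- c(diff_cat, dk)
    worse_cont <- if (is.na(dc)) TRUE else dc > prev_cont
    worse_cat <- if (is.na(dk)) TRUE else dk > prev_cat
    if (worse_cont && worse_cat) { converged <- TRUE; break }  # keep previous iterate
    best <- x
    prev_cont <- if (!is.na(dc)) dc else prev_cont
    prev_cat <- if (!is.na(dk)) dk else prev_cat
  }

  table[covs] <- best
  list(table = table,
       diagnostics = list(iterations = iter, diff_continuous = diff_cont,
                          diff_categorical = diff_cat, converged = converged))
}

#' Mask covariate cells completely at random
#'
#' Test harness for imputation quality: each covariate cell is
#' independently set missing with probability `rate`; the original table
#' is returned alongside for scoring.
#'
#' @param table trial table.
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `table` (masked), `mask` (named list of masked row
#'   indices per covariate) and `original`.
#' @export
mask_mcar <- function(table, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  set.seed(seed)
  original <- table
  covs <- trial_covariate_names(table)
  mask <- list()
  for (v in covs) {
    idx <- which(stats::runif(nrow(table)) < rate & !is.na(table[[v]]))
    mask[[v]] <- idx
    table[[v]][idx] <- NA
  }
  list(table = table, mask = mask, original = original)
}
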