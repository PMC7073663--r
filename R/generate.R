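sample_covariates <- function(schema, n) {
  out <- list()
  for (cv in schema) {
    x <- switch(cv$kind,
      continuous = {
        z <- stats::rnorm(n, cv$mean, cv$sd)
        if (!is.null(cv$lower)) z <- pmax(cv$lower, z)
        if (!is.null(cv$upper)) z <- pmin(cv$upper, z)
        if (!is.null(cv$digits)) z <- round(z, cv$digits)
        z
      },
      count = stats::rpois(n, cv$lambda),
      binary = factor(sample(cv$levels, n, replace = TRUE,
                             prob = c(1 - cv$prob, cv$prob)),
                      levels = cv$levels),
      nominal = factor(sample(cv$levels, n, replace = TRUE, prob = cv$probs),
                       levels = cv$levels)
    )
    out[[cv$name]] <- x
  }
  as.data.frame(out, optional = TRUE)
}

# 1:1 block randomization; exact balance inside every even block, a single
# (possibly smaller) final block absorbs the remainder
block_randomize <- function(n, block_sizes) {
  sizes <- integer(0); total <- 0L
  while (total < n) {
    b <- block_sizes[sample.int(length(block_sizes), 1L)]
    if (total + b > n) b <- n - total
    sizes <- c(sizes, b); total <- total + b
  }
  arms <- unlist(lapply(sizes, function(b) {
    half <- b %/% 2L
    block <- c(rep("TAU", half), rep("BLEND", half))
    if (b %% 2L == 1L) block <- c(block, sample(c("TAU", "BLEND"), 1L))
    sample(block)
  }))
  factor(arms, levels = c("TAU", "BLEND"))
}

#' Generate a two-arm trial table with known ground truth
#'
#' Draws baseline covariates from the scenario schema, assigns arms by
#' 1:1 block randomization, computes each patient's expected 12-week
#' outcome under *both* arms from the arm-specific linear models (the
#' ground truth, recorded before noise is added and before the outcome is
#' clipped to the 0-27 integer scale), then produces the observed table:
#' outcome = linear predictor of the assigned arm + Gaussian noise,
#' clipped and rounded; covariate missingness injected per covariate
#' (completely at random by default, or logistic in a designated
#' covariate when the missing-at-random hook is set); a dropout fraction
#' of outcomes set missing.
#'
#' @param config a [scenario_config()].
#' @return list with `table` (trial table; `schema` attribute carries the
#'   covariate schema) and `truth` (per patient: `mu_tau`, `mu_blend`,
#'   `true_pai` = |mu_tau - mu_blend|, `true_optimal` in
#'   TAU/BLEND/either).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  covdf <- sample_covariates(config$covariates, n)
  arm <- block_randomize(n, config$block_sizes)

  full <- data.frame(patient_id = ids, arm = arm, covdf,
                     outcome = 0L, check.names = FALSE)
  attr(full, "schema") <- config$covariates
  x <- encode(full)$x
  stopifnot(identical(colnames(x), config$columns))

  mu_tau <- drop(config$intercept_tau + x %*% config$beta_tau)
  mu_blend <- drop(config$intercept_blend + x %*% config$beta_blend)
  truth <- data.frame(
    patient_id = ids,
    arm = as.character(arm),
    mu_tau = mu_tau, mu_blend = mu_blend,
    true_pai = abs(mu_tau - mu_blend),
    true_optimal = ifelse(mu_tau == mu_blend, "either",
                          ifelse(mu_tau < mu_blend, "TAU", "BLEND")),
    stringsAsFactors = FALSE
  )

  mu <- ifelse(arm == "TAU", mu_tau, mu_blend)
  latent <- mu + stats::rnorm(n, 0, config$noise_sd)
  outcome <- as.integer(round(pmin(27, pmax(0, latent))))

  # missingness applied after truth/outcome so the truth never depends on it
  for (cv in config$covariates) {
    rate <- config$miss_rates[[cv$name]]
    if (rate <= 0) next
    if (!is.null(config$mar_covariate)) {
      z <- as.numeric(scale(as.numeric(covdf[[config$mar_covariate]])))
      p <- stats::plogis(stats::qlogis(rate) + config$mar_strength * z)
    } else p <- rate
    mask <- stats::runif(n) < p
    covdf[[cv$name]][mask] <- NA
  }
  if (config$outcome_dropout_rate > 0)
    outcome[stats::runif(n) < config$outcome_dropout_rate] <- NA

  table <- data.frame(patient_id = ids, arm = arm, covdf,
                      outcome = outcome, check.names = FALSE)
  attr(table, "schema") <- config$covariates
  list(table = table, truth = truth)
}

schema_to_json <- function(schema) {
  lapply(schema, function(cv) Filter(Negate(is.null), unclass(cv)))
}

json_to_schema <- function(js) {
  lapply(js, function(e) {
    e$levels <- if (!is.null(e$levels)) unlist(e$levels)
    e$probs <- if (!is.null(e$probs)) unlist(e$probs)
    structure(Filter(Negate(is.null), e), class = "pairct_covariate")
  })
}

#' Write / read a trial table as CSV with a JSON sidecar
#'
#' The CSV uses a header row, empty cells for missing values and
#' TAU/BLEND arm labels. A `<path>.meta.json` sidecar carries the
#' covariate schema (kinds and factor levels) so that a round trip is
#' lossless, plus optionally the ground-truth record.
#'
#' @param table trial table.
#' @param path CSV destination.
#' @param truth optional truth data frame stored in the sidecar.
#' @return `write_trial`: the path, invisibly. `read_trial`: the trial
#'   table (with `truth` attribute when the sidecar holds one).
#' @export
write_trial <- function(table, path, truth = NULL) {
  validate_trial(table)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  side <- list(schema = schema_to_json(trial_schema(table)))
  if (!is.null(truth)) side$truth <- truth
  write_json_stable(side, paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  raw <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                         check.names = FALSE)
  side_path <- paste0(path, ".meta.json")
  schema <- NULL; truth <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = FALSE)
    schema <- json_to_schema(side$schema)
    if (!is.null(side$truth)) {
      fields <- names(side$truth[[1L]])
      truth <- as.data.frame(stats::setNames(lapply(fields, function(f)
        unlist(lapply(side$truth, `[[`, f))), fields))
    }
  }
  if (!"outcome" %in% names(raw) || !"arm" %in% names(raw))
    stop("malformed trial file: required column 'arm' or 'outcome' absent",
         call. = FALSE)
  if (!is.numeric(raw$outcome) && !all(is.na(raw$outcome))) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw$outcome))) & !is.na(raw$outcome))
    stop(sprintf("malformed trial file: non-numeric outcome at row %d", bad[1L]),
         call. = FALSE)
  }
  raw$outcome <- as.integer(raw$outcome)
  raw$arm <- factor(raw$arm, levels = c("TAU", "BLEND"))
  if (anyNA(raw$arm))
    stop("unknown arm label at row ", which(is.na(raw$arm))[1L], call. = FALSE)
  if (!is.null(schema)) {
    for (cv in schema) {
      if (cv$kind %in% c("binary", "nominal"))
        raw[[cv$name]] <- factor(raw[[cv$name]], levels = cv$levels)
      else if (cv$kind == "count")
        raw[[cv$name]] <- as.integer(raw[[cv$name]])
    }
    attr(raw, "schema") <- schema
  } else {
    for (v in trial_covariate_names(raw))
      if (is.character(raw[[v]])) raw[[v]] <- factor(raw[[v]], levels = sort(unique(raw[[v]][!is.na(raw[[v]])])))
  }
  validate_trial(raw)
  if (!is.null(truth)) attr(raw, "truth") <- truth
  raw
}
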