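#' Covariate schema helpers
#'
#' A trial scenario describes each baseline covariate by name, kind and
#' distribution parameters. Four kinds are supported: `continuous`
#' (Gaussian, optionally clamped/rounded), `count` (Poisson), `binary`
#' (two-level factor) and `nominal` (k-level factor). Factor levels are
#' always stored sorted so that encoding is deterministic.
#'
#' @param name covariate name (must be a valid column name).
#' @param mean,sd Gaussian location/scale for `cov_continuous`.
#' @param lower,upper optional clamping bounds applied after sampling.
#' @param digits optional rounding applied after clamping.
#' @param lambda Poisson mean for `cov_count`.
#' @param prob probability of the second (sorted) level for `cov_binary`.
#' @param levels factor levels; sorted internally.
#' @param probs sampling probabilities aligned to the *sorted* levels.
#' @return a schema entry (list) consumed by [scenario_config()].
#' @export
cov_continuous <- function(name, mean, sd, lower = NULL, upper = NULL, digits = NULL) {
  stopifnot(is.character(name), length(name) == 1L, sd > 0)
  structure(list(name = name, kind = "continuous", mean = mean, sd = sd,
                 lower = lower, upper = upper, digits = digits),
            class = "pairct_covariate")
}

#' @rdname cov_continuous
#' @export
cov_count <- function(name, lambda) {
  stopifnot(lambda >= 0)
  structure(list(name = name, kind = "count", lambda = lambda),
            class = "pairct_covariate")
}

#' @rdname cov_continuous
#' @export
cov_binary <- function(name, prob, levels = c("no", "yes")) {
  stopifnot(length(levels) == 2L, prob >= 0, prob <= 1)
  levels <- sort(levels)
  structure(list(name = name, kind = "binary", levels = levels, prob = prob),
            class = "pairct_covariate")
}

#' @rdname cov_continuous
#' @export
cov_nominal <- function(name, levels, probs = NULL) {
  stopifnot(length(levels) >= 2L, anyDuplicated(levels) == 0L)
  ord <- order(levels)
  levels <- levels[ord]
  if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
  else {
    stopifnot(length(probs) == length(levels), all(probs >= 0))
    probs <- probs[ord] / sum(probs)
  }
  structure(list(name = name, kind = "nominal", levels = levels, probs = probs),
            class = "pairct_covariate")
}

#' Encoded design-column names implied by a covariate schema
#'
#' Continuous and count covariates contribute one column under their own
#' name; a binary covariate one indicator column for its second sorted
#' level; a k-level nominal k-1 indicator columns named
#' `<name>_<level>` against the first sorted level as reference.
#'
#' @param schema list of schema entries.
#' @return character vector of design-column names in deterministic order.
#' @export
schema_columns <- function(schema) {
  unlist(lapply(schema, function(cv) {
    switch(cv$kind,
      continuous = ,
      count = cv$name,
      binary = cv$name,
      nominal = paste(cv$name, cv$levels[-1L], sep = "_")
    )
  }), use.names = FALSE)
}

#' Build a full trial scenario configuration
#'
#' Bundles everything the generator needs: cohort size, covariate schema,
#' arm-specific linear outcome models on the encoded design scale,
#' Gaussian noise, per-covariate missingness, outcome dropout and the
#' block-randomization scheme. `beta_tau` / `beta_blend` may name only the
#' nonzero coefficients; all other design columns get zero.
#'
#' @param n_patients cohort size.
#' @param covariates list of schema entries (see [cov_continuous()]).
#' @param beta_tau,beta_blend named numeric vectors of outcome points per
#'   design-column unit; names must be encoded column names.
#' @param intercept_tau,intercept_blend arm intercepts (outcome points).
#' @param noise_sd residual standard deviation (> 0, outcome points).
#' @param miss_rates named per-covariate missingness fractions in `[0, 1)`;
#'   unnamed covariates default to 0. Values at or above 0.5 are allowed
#'   (to exercise the screening rule) but flagged with a warning.
#' @param outcome_dropout_rate fraction of patients with missing outcome.
#' @param block_sizes multiset of even block sizes in `[8, 14]` used for
#'   1:1 block randomization.
#' @param mar_covariate,mar_strength optional missing-at-random hook: if
#'   set, each covariate's missingness probability becomes logistic in the
#'   standardized value of `mar_covariate` with slope `mar_strength`
#'   (default is missing completely at random).
#' @param seed integer master seed for all randomness.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_patients, covariates,
                            beta_tau = numeric(), beta_blend = numeric(),
                            intercept_tau = 0, intercept_blend = 0,
                            noise_sd = 1,
                            miss_rates = NULL,
                            outcome_dropout_rate = 0,
                            block_sizes = c(8L, 10L, 12L, 14L),
                            mar_covariate = NULL, mar_strength = 0,
                            seed = 1L) {
  stopifnot(n_patients >= 1, noise_sd > 0,
            outcome_dropout_rate >= 0, outcome_dropout_rate <= 0.1)
  if (!all(block_sizes %% 2 == 0 & block_sizes >= 2 & block_sizes <= 14))
    stop("block_sizes must be even integers no larger than 14", call. = FALSE)
  cov_names <- vapply(covariates, `[[`, "", "name")
  if (anyDuplicated(cov_names)) stop("duplicate covariate names", call. = FALSE)
  cols <- schema_columns(covariates)

  expand_beta <- function(beta, label) {
    full <- stats::setNames(numeric(length(cols)), cols)
    if (length(beta)) {
      bad <- setdiff(names(beta), cols)
      if (length(bad))
        stop(sprintf("%s names not among design columns: %s", label,
                     paste(bad, collapse = ", ")), call. = FALSE)
      full[names(beta)] <- beta
    }
    full
  }
  rates <- stats::setNames(numeric(length(cov_names)), cov_names)
  if (!is.null(miss_rates)) {
    bad <- setdiff(names(miss_rates), cov_names)
    if (length(bad))
      stop("miss_rates for unknown covariates: ", paste(bad, collapse = ", "),
           call. = FALSE)
    stopifnot(all(miss_rates >= 0), all(miss_rates < 1))
    rates[names(miss_rates)] <- miss_rates
    if (any(miss_rates >= 0.5))
      warning("miss_rates at or above 0.5 will be removed by default screening")
  }
  if (!is.null(mar_covariate) && !mar_covariate %in% cov_names)
    stop("mar_covariate not in schema", call. = FALSE)

  structure(list(
    n_patients = as.integer(n_patients),
    covariates = covariates,
    columns = cols,
    beta_tau = expand_beta(beta_tau, "beta_tau"),
    beta_blend = expand_beta(beta_blend, "beta_blend"),
    intercept_tau = intercept_tau,
    intercept_blend = intercept_blend,
    noise_sd = noise_sd,
    miss_rates = rates,
    outcome_dropout_rate = outcome_dropout_rate,
    block_sizes = as.integer(block_sizes),
    mar_covariate = mar_covariate,
    mar_strength = mar_strength,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Two-arm trial scenario: n = %d, %d covariates (%d design columns)\n",
              x$n_patients, length(x$covariates), length(x$columns)))
  cat(sprintf("  noise_sd = %g, outcome dropout = %g, seed = %d\n",
              x$noise_sd, x$outcome_dropout_rate, x$seed))
  nz <- union(names(which(x$beta_tau != 0)), names(which(x$beta_blend != 0)))
  cat("  active columns:", if (length(nz)) paste(nz, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
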