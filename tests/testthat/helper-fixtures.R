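# shared fixtures, all generated in code

# minimal hand-built trial table
toy_table <- function(n = 10, n_missing_outcome = 0, extra = NULL) {
  tab <- data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    arm = factor(rep(c("TAU", "BLEND"), length.out = n), levels = c("TAU", "BLEND")),
    severity = round(seq(5, 25, length.out = n)),
    chronic = factor(rep(c("no", "yes"), length.out = n), levels = c("no", "yes")),
    outcome = as.integer(round(seq(3, 20, length.out = n)))
  )
  if (n_missing_outcome > 0) tab$outcome[seq_len(n_missing_outcome)] <- NA
  if (!is.null(extra)) tab <- cbind(tab[-ncol(tab)], extra, outcome = tab$outcome)
  tab
}

# exact-arithmetic scenario: integer-valued linear predictors inside the
# 0-27 scale and near-zero noise, so the observed outcome equals the
# truth linear predictor after integer rounding
exact_scenario <- function(n = 120, seed = 1, prescriptive = 0) {
  scenario_config(
    n_patients = n,
    covariates = list(
      cov_count("visits", lambda = 2),
      cov_binary("marker", prob = 0.5)
    ),
    beta_tau = c(visits = 2, marker = prescriptive),
    beta_blend = c(visits = 2, marker = -prescriptive),
    intercept_tau = 5, intercept_blend = 5,
    noise_sd = 1e-9, seed = seed
  )
}

# correlated mixed-type table for imputation tests (AR(1) Gaussian block
# plus one category derived from the first coordinate)
correlated_table <- function(n = 150, seed = 1, rho = 0.7, p = 6) {
  set.seed(seed)
  S <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(S)
  df <- as.data.frame(z)
  names(df) <- paste0("v", seq_len(p))
  df$cat1 <- factor(ifelse(z[, 1] + stats::rnorm(n, 0, 0.5) > 0, "hi", "lo"))
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             arm = factor(rep(c("TAU", "BLEND"), length.out = n),
                          levels = c("TAU", "BLEND")),
             df, outcome = 10L)
}

# sum of squared imputation errors on masked cells, for a masked table,
# against mean imputation on the same mask
imputation_sq_errors <- function(masked, imputed, numeric_vars) {
  sq_rf <- sq_mean <- 0
  for (v in numeric_vars) {
    idx <- masked$mask[[v]]
    if (!length(idx)) next
    truth <- masked$original[[v]][idx]
    sq_rf <- sq_rf + sum((imputed$table[[v]][idx] - truth)^2)
    mval <- mean(masked$table[[v]], na.rm = TRUE)
    sq_mean <- sq_mean + sum((mval - truth)^2)
  }
  c(rf = sq_rf, mean = sq_mean)
}

# independent normal-equations LOO oracle: refit without row i via
# solve(X'X, X'y) on the intercept-augmented design
loo_oracle <- function(x, y, i) {
  xd <- cbind(1, x)
  xi <- xd[-i, , drop = FALSE]
  beta <- solve(t(xi) %*% xi, t(xi) %*% y[-i])
  drop(xd[i, ] %*% beta)
}

# build a coded_matrix by hand for PAI unit tests
manual_coded <- function(x, y, arm, ids = sprintf("%s%02d", arm[1], seq_along(y))) {
  structure(list(
    x = x,
    meta = data.frame(column = colnames(x), source = colnames(x),
                      category = "continuous", reference = NA_character_),
    patient_id = ids, arm = arm, outcome = y
  ), class = "coded_matrix")
}
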