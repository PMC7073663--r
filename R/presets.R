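#' Built-in trial scenarios
#'
#' Four fully specified scenarios used throughout the package's tests and
#' analyses:
#'
#' * `null` — a calibration scenario with a single prognostic driver
#'   (baseline depression severity, positive coefficient in both arms) and
#'   no prescriptive effects: both arms share the same outcome model, so
#'   the true per-patient advantage is zero everywhere.
#' * `prognostic_only` — several prognostic covariates (severity,
#'   expectancy, quality of life) with identical coefficients in both
#'   arms; still no differential response.
#' * `prescriptive` — n = 500 with one binary prescriptive covariate
#'   carrying +4 / -4 point arm-specific effects and an arm intercept gap
#'   of -4, so the arm contrast is -4 + 8 x: the truly optimal arm flips
#'   with x and every patient's true advantage is 4 PHQ-9 points;
#'   residual noise_sd = 4.
#' * `ecompared_like` — mimics the secondary-care blended-treatment trial
#'   table: n = 251, 1:1 block randomization with blocks of 8-14,
#'   28 candidate baseline predictors across sociodemographic,
#'   symptomatology/quality-of-life, healthcare-utilization and patient-
#'   expectancy categories (including a 4-level country and a 5-level
#'   marital-status nominal), per-item missingness spanning 1.2-40.8%,
#'   and a small completer-dropout rate in the 12-week outcome.
#'
#' @param name one of `"null"`, `"prognostic_only"`, `"prescriptive"`,
#'   `"ecompared_like"`.
#' @param seed master seed stored in the returned config.
#' @return a [scenario_config()].
#' @export
preset <- function(name, seed = 1L) {
  known <- c("null", "prognostic_only", "prescriptive", "ecompared_like")
  if (!is.character(name) || length(name) != 1L || !name %in% known)
    stop("unknown preset; available presets: ", paste(known, collapse = ", "),
         call. = FALSE)
  switch(name,
    null = preset_null(seed),
    prognostic_only = preset_prognostic(seed),
    prescriptive = preset_prescriptive(seed),
    ecompared_like = preset_ecompared(seed)
  )
}

preset_null <- function(seed) {
  scenario_config(
    n_patients = 200,
    covariates = list(
      cov_continuous("phq9_baseline", mean = 15, sd = 4, lower = 5, upper = 27, digits = 0),
      cov_continuous("age", mean = 41, sd = 13.7, lower = 18, digits = 0),
      cov_binary("antidepressants", prob = 0.5),
      cov_count("gp_visits", lambda = 2),
      cov_continuous("eq5d", mean = 0.6, sd = 0.2)
    ),
    beta_tau = c(phq9_baseline = 0.6),
    beta_blend = c(phq9_baseline = 0.6),
    intercept_tau = 2, intercept_blend = 2,
    noise_sd = 4, seed = seed
  )
}

preset_prognostic <- function(seed) {
  beta <- c(phq9_baseline = 0.6, ceq_expectancy = -0.3, eq5d = -3)
  scenario_config(
    n_patients = 300,
    covariates = list(
      cov_continuous("phq9_baseline", mean = 15, sd = 4, lower = 5, upper = 27, digits = 0),
      cov_continuous("ceq_expectancy", mean = 14, sd = 5),
      cov_continuous("eq5d", mean = 0.6, sd = 0.2),
      cov_binary("recurrent_depression", prob = 0.55),
      cov_count("psychiatrist_visits", lambda = 1)
    ),
    beta_tau = beta, beta_blend = beta,
    intercept_tau = 4, intercept_blend = 4,
    noise_sd = 4, seed = seed
  )
}

preset_prescriptive <- function(seed) {
  scenario_config(
    n_patients = 500,
    covariates = list(
      cov_continuous("phq9_baseline", mean = 15, sd = 4, lower = 5, upper = 27, digits = 0),
      cov_binary("online_affinity", prob = 0.5),
      cov_continuous("age", mean = 41, sd = 13.7, lower = 18, digits = 0),
      cov_continuous("eq5d", mean = 0.6, sd = 0.2),
      cov_count("gp_visits", lambda = 2)
    ),
    beta_tau = c(phq9_baseline = 0.5, online_affinity = 4),
    beta_blend = c(phq9_baseline = 0.5, online_affinity = -4),
    intercept_tau = 6, intercept_blend = 10,
    noise_sd = 4, seed = seed
  )
}

preset_ecompared <- function(seed) {
  covs <- list(
    # sociodemographic
    cov_continuous("age", mean = 41, sd = 13.7, lower = 18, upper = 80, digits = 0),
    cov_binary("female", prob = 0.682),
    cov_nominal("country", levels = c("Denmark", "France", "Netherlands", "Switzerland"),
                probs = c(0.159, 0.322, 0.339, 0.180)),
    cov_nominal("marital_status",
                levels = c("divorced", "living_together", "married", "single", "widowed"),
                probs = c(0.12, 0.21, 0.31, 0.32, 0.04)),
    cov_nominal("education", levels = c("primary", "secondary", "tertiary"),
                probs = c(0.2, 0.45, 0.35)),
    # symptomatology, treatment history and quality of life
    cov_continuous("phq9_baseline", mean = 15, sd = 4.5, lower = 5, upper = 27, digits = 0),
    cov_binary("recurrent_depression", prob = 0.56),
    cov_binary("melancholic_episode", prob = 0.40),
    cov_binary("dysthymia", prob = 0.07),
    cov_binary("comorbid_anxiety", prob = 0.54),
    cov_binary("antidepressants", prob = 0.51),
    cov_binary("prior_psychotherapy", prob = 0.45),
    cov_nominal("therapy_preference", levels = c("blended", "no_preference", "tau"),
                probs = c(0.4, 0.3, 0.3)),
    cov_continuous("eq5d", mean = 0.55, sd = 0.25, lower = -0.2, upper = 1),
    # healthcare utilization over the previous four months
    cov_count("gp_visits", lambda = 2),
    cov_count("psychiatrist_visits", lambda = 1),
    cov_count("psychologist_visits", lambda = 1.5),
    cov_count("outpatient_psychotherapy_days", lambda = 2),
    cov_count("daytime_treatment_days", lambda = 0.5),
    cov_count("hospital_admissions", lambda = 0.3),
    cov_count("hospital_days", lambda = 1),
    cov_count("self_help_visits", lambda = 0.5),
    cov_count("social_worker_visits", lambda = 0.5),
    cov_count("physiotherapy_visits", lambda = 1),
    cov_count("alternative_medicine_visits", lambda = 0.8),
    cov_count("medication_count", lambda = 1.5),
    # patient expectancy
    cov_continuous("ceq_credibility", mean = 18, sd = 4, lower = 3, upper = 27, digits = 0),
    cov_continuous("ceq_expectancy", mean = 14, sd = 5, lower = 3, upper = 27, digits = 0)
  )
  scenario_config(
    n_patients = 251,
    covariates = covs,
    beta_tau = c(phq9_baseline = 0.55, ceq_expectancy = -0.25,
                 outpatient_psychotherapy_days = -0.5, psychiatrist_visits = 0.8,
                 daytime_treatment_days = 1.0,
                 country_France = 1.0, country_Netherlands = 1.0,
                 country_Switzerland = 1.0),
    beta_blend = c(phq9_baseline = 0.5, ceq_expectancy = -0.2,
                   hospital_admissions = 2.0, eq5d = -3.0,
                   self_help_visits = 1.0, marital_status_widowed = 2.0,
                   ceq_credibility = -0.1),
    intercept_tau = 3, intercept_blend = 4.5,
    noise_sd = 5,
    miss_rates = c(
      ceq_credibility = 0.037, ceq_expectancy = 0.041, eq5d = 0.016,
      antidepressants = 0.012, prior_psychotherapy = 0.404,
      melancholic_episode = 0.143, dysthymia = 0.053, comorbid_anxiety = 0.024,
      gp_visits = 0.02, psychiatrist_visits = 0.05, psychologist_visits = 0.08,
      outpatient_psychotherapy_days = 0.10, daytime_treatment_days = 0.15,
      hospital_admissions = 0.12, hospital_days = 0.20, self_help_visits = 0.25,
      social_worker_visits = 0.30, physiotherapy_visits = 0.35,
      alternative_medicine_visits = 0.38, medication_count = 0.408
    ),
    outcome_dropout_rate = 0.024,
    block_sizes = c(8L, 10L, 12L, 14L),
    seed = seed
  )
}
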