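test_that("identical arm models give zero true advantage everywhere", {
  cfg <- exact_scenario(n = 80, seed = 3, prescriptive = 0)
  g <- generate_trial(cfg)
  expect_true(all(g$truth$true_pai == 0))
  expect_true(all(g$truth$true_optimal == "either"))
})

test_that("block randomization balances arms exactly within full blocks", {
  cfg <- preset("ecompared_like", seed = 5)
  g <- generate_trial(cfg)
  expect_equal(nrow(g$table), 251)
  # arm sizes differ by at most one incomplete final block
  counts <- table(g$table$arm)
  expect_lte(abs(counts[["TAU"]] - counts[["BLEND"]]), max(cfg$block_sizes))
  # forced balance on an exactly blocked cohort (n divisible by block size)
  cfg2 <- scenario_config(n_patients = 96,
                          covariates = list(cov_count("v", lambda = 1)),
                          beta_tau = c(v = 1), beta_blend = c(v = 1),
                          noise_sd = 1, block_sizes = 8L, seed = 2)
  g2 <- generate_trial(cfg2)
  expect_equal(unname(table(g2$table$arm)[["TAU"]]), 48)
})

test_that("with negligible noise the observed outcome equals the linear predictor", {
  g <- generate_trial(exact_scenario(n = 150, seed = 7))
  mu <- ifelse(g$table$arm == "TAU", g$truth$mu_tau, g$truth$mu_blend)
  expect_true(all(mu == round(mu)))  # integer by construction
  expect_equal(as.numeric(g$table$outcome), mu)
})

test_that("realized missingness matches the configured rates and truth ignores the mask", {
  covs <- list(cov_continuous("a", 0, 1), cov_continuous("b", 0, 1))
  base <- list(n_patients = 3000, covariates = covs,
               beta_tau = c(a = 1), beta_blend = c(a = 1), noise_sd = 1, seed = 11)
  cfg1 <- do.call(scenario_config, c(base, list(miss_rates = c(a = 0.3, b = 0.05))))
  cfg2 <- do.call(scenario_config, c(base, list(miss_rates = c(a = 0.45))))
  g1 <- generate_trial(cfg1)
  g2 <- generate_trial(cfg2)
  rate_a <- mean(is.na(g1$table$a))
  expect_lt(abs(rate_a - 0.3), 3 * sqrt(0.3 * 0.7 / 3000))
  expect_lt(abs(mean(is.na(g1$table$b)) - 0.05), 3 * sqrt(0.05 * 0.95 / 3000))
  # same seed, different masks: the truth record is identical
  expect_identical(g1$truth, g2$truth)
})

test_that("presets are fully specified and deterministic", {
  expect_error(preset("nope"), "available presets")
  cfg <- preset("ecompared_like")
  expect_equal(cfg$n_patients, 251)
  expect_equal(length(cfg$covariates), 28)
  expect_true(any(vapply(cfg$covariates, function(cv)
    cv$kind == "nominal" && length(cv$levels) == 4, TRUE)))
  expect_equal(unname(range(cfg$miss_rates[cfg$miss_rates > 0])), c(0.012, 0.408))
  # null preset: no prescriptive contrast, positive severity slope in both arms
  nul <- preset("null")
  expect_identical(nul$beta_tau, nul$beta_blend)
  expect_gt(nul$beta_tau[["phq9_baseline"]], 0)
  # determinism: identical outputs from identical configs
  expect_identical(generate_trial(preset("prescriptive", seed = 9)),
                   generate_trial(preset("prescriptive", seed = 9)))
})

test_that("trial CSV round trip is lossless and validates arm labels", {
  g <- generate_trial(preset("ecompared_like", seed = 4))
  path <- file.path(withr::local_tempdir(), "trial.csv")
  write_trial(g$table, path, truth = g$truth)
  back <- read_trial(path)
  expect_equal(back$outcome, g$table$outcome)
  expect_equal(as.character(back$arm), as.character(g$table$arm))
  for (v in setdiff(names(g$table), c("patient_id", "arm", "outcome"))) {
    expect_equal(is.na(back[[v]]), is.na(g$table[[v]]), info = v)
    if (is.factor(g$table[[v]]))
      expect_identical(levels(back[[v]]), levels(g$table[[v]]))
    expect_equal(as.character(back[[v]]), as.character(g$table[[v]]), info = v)
  }
  expect_s3_class(attr(back, "truth"), "data.frame")

  # empty cells are missing values, not empty-string categories
  lines <- readLines(path)
  expect_true(any(grepl(",,", lines)))
  expect_false(any(vapply(back[sapply(back, is.factor)], function(f) "" %in% levels(f), TRUE)))

  # unknown arm labels are rejected
  bad <- g$table
  bad$arm <- as.character(bad$arm)
  bad$arm[3] <- "PLACEBO"
  badpath <- file.path(withr::local_tempdir(), "bad.csv")
  utils::write.csv(bad, badpath, row.names = FALSE, na = "")
  expect_error(read_trial(badpath), "arm label")
})
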