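test_that("predictor selection follows the chosen rule", {
  fake <- structure(list(
    columns = c("a", "b", "c"),
    gamma = matrix(c(TRUE, FALSE, TRUE), 1, 3),
    pip = c(a = 0.99, b = 0.51, c = 0.49),
    n_models_evaluated = 8L
  ), class = "bma_result")
  expect_identical(as.character(select_predictors(fake)), c("a", "c"))
  mpm <- select_predictors(fake, "median_probability_model")
  expect_identical(as.character(mpm), c("a", "b"))
  empty <- fake; empty$pip <- c(a = 0.2, b = 0.1, c = 0.3)
  expect_warning(sel <- select_predictors(empty, "median_probability_model"),
                 "intercept only")
  expect_true(attr(sel, "null_model"))
})

test_that("the two selection rules can disagree on correlated predictors", {
  set.seed(17)
  n <- 60
  x1 <- rnorm(n); x2 <- x1 + rnorm(n, 0, 0.4); x3 <- rnorm(n)
  x <- cbind(x1 = x1, x2 = x2, x3 = x3)
  y <- 1 + x1 + rnorm(n)
  e <- enumerate_models(x, y, bma_config())
  hpm <- select_predictors(e, "highest_posterior_model")
  mpm <- select_predictors(e, "median_probability_model")
  expect_false(setequal(hpm, mpm))
  expect_true(any(!(mpm %in% hpm)))  # a pip > 0.5 column outside the top model
})

test_that("leave-one-out factual predictions match the normal-equations oracle", {
  set.seed(31)
  n <- 8
  x <- cbind(s1 = rnorm(n, 10, 3), s2 = rnorm(n))
  y <- round(5 + 0.8 * x[, 1] - 2 * x[, 2] + rnorm(n))
  other_x <- cbind(s1 = rnorm(12, 10, 3), s2 = rnorm(12))
  other_y <- round(5 + 0.5 * other_x[, 1] + rnorm(12))
  arm <- manual_coded(x, y, rep("TAU", n))
  oth <- manual_coded(other_x, other_y, rep("BLEND", 12))
  preds <- loo_predictions(arm, oth, c("s1", "s2"), c("s1", "s2"))
  for (i in seq_len(n))
    expect_lt(abs(preds$factual_pred[i] - loo_oracle(x, y, i)), 1e-8)
  # lower predicted score under the received arm marks it optimal
  lower <- preds$factual_pred < preds$counterfactual_pred
  expect_identical(preds$optimal_arm[lower], rep("TAU", sum(lower)))
  expect_equal(preds$pai, abs(preds$factual_pred - preds$counterfactual_pred))
})

test_that("identical arms with an exact linear signal produce zero PAI", {
  set.seed(32)
  n <- 20
  x <- cbind(v = rnorm(n, 0, 2))
  y <- 10 + 1.5 * x[, 1]  # noiseless: every least-squares fit is the same line
  a <- manual_coded(x, y, rep("TAU", n))
  b <- manual_coded(x, y, rep("BLEND", n), ids = sprintf("B%02d", 1:n))
  preds <- loo_predictions(a, b, "v", "v")
  expect_lt(max(preds$pai), 1e-8)
})

test_that("a patient's own outcome never influences their prediction pair", {
  set.seed(33)
  n <- 15
  x <- cbind(v = rnorm(n))
  y <- round(10 + 2 * x[, 1] + rnorm(n))
  ox <- cbind(v = rnorm(n)); oy <- round(9 + 2 * ox[, 1] + rnorm(n))
  a1 <- manual_coded(x, y, rep("TAU", n))
  y2 <- y; y2[4] <- y2[4] + 13L
  a2 <- manual_coded(x, y2, rep("TAU", n))
  oth <- manual_coded(ox, oy, rep("BLEND", n), ids = sprintf("B%02d", 1:n))
  p1 <- loo_predictions(a1, oth, "v", "v")
  p2 <- loo_predictions(a2, oth, "v", "v")
  expect_equal(p1$factual_pred[4], p2$factual_pred[4], tolerance = 1e-10)
  expect_equal(p1$counterfactual_pred, p2$counterfactual_pred, tolerance = 1e-12)
})

test_that("PAI summaries partition the cohort and handle the all-tied case", {
  preds <- data.frame(
    patient_id = sprintf("X%02d", 1:6),
    received_arm = rep(c("TAU", "BLEND"), 3),
    factual_pred = c(5, 8, 10, 4, 7, 12),
    counterfactual_pred = c(5, 8, 10, 4, 7, 12),
    optimal_arm = rep(c("TAU", "BLEND"), 3),
    pai = rep(0, 6),
    received_optimal = rep(TRUE, 6),
    observed_outcome = c(6, 9, 11, 3, 8, 13)
  )
  s <- summarize_pai(preds)
  expect_equal(s$mean_pai, 0)
  expect_equal(s$frac_pai_ge_threshold, 0)
  expect_equal(s$n_optimal, 6)
  expect_equal(s$n_suboptimal, 0)
  expect_equal(s$n_optimal + s$n_suboptimal, s$n)
  expect_equal(s$mean_absolute_error, mean(abs(preds$factual_pred - preds$observed_outcome)))
  # permutation invariance of every reported statistic
  s2 <- summarize_pai(preds[sample(6), ])
  expect_equal(unclass(s2), unclass(s))
})
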