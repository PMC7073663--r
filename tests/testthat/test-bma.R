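test_that("two-model normalization: pip equals bf/(1+bf) for a single predictor", {
  set.seed(21)
  n <- 80
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x1"))
  y <- 0.6 * x[, 1] + rnorm(n)
  e <- enumerate_models(x, y, bma_config())
  bf <- exp(e$log_marginal[which(e$p_gamma == 1)])
  expect_equal(unname(e$pip["x1"]), bf / (1 + bf), tolerance = 1e-12)
  expect_equal(sum(e$posterior_prob), 1, tolerance = 1e-10)
})

test_that("posterior mass normalizes and unidentifiable models get zero mass", {
  set.seed(22)
  x <- matrix(rnorm(6 * 5), 6, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(6)
  expect_warning(e <- enumerate_models(x, y, bma_config()), "zero mass")
  expect_equal(sum(e$posterior_prob), 1, tolerance = 1e-10)
  expect_true(all(e$posterior_prob[e$p_gamma >= 5] == 0))
  expect_gt(e$n_skipped, 0)
})

test_that("mirror-image columns receive exactly equal inclusion probabilities", {
  set.seed(23)
  n <- 100
  a <- rnorm(n)
  x <- cbind(xp = a, xn = -a, z = rnorm(n))
  y <- a + rnorm(n)
  e <- enumerate_models(x, y, bma_config())
  # xn = -xp carries identical information; every model containing one is
  # matched by one containing the other with the same R^2
  expect_equal(unname(e$pip["xp"]), unname(e$pip["xn"]), tolerance = 1e-9)
})

test_that("Bayes factors and inclusion probabilities are scale invariant in y", {
  set.seed(24)
  n <- 90
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- x[, 2] - 0.5 * x[, 4] + rnorm(n)
  e1 <- enumerate_models(x, y, bma_config())
  e2 <- enumerate_models(x, y * 37.5, bma_config())
  expect_equal(e1$pip, e2$pip, tolerance = 1e-12)
  expect_equal(e1$log_marginal, e2$log_marginal, tolerance = 1e-9)
})

test_that("the sampler reproduces enumeration exactly when the budget exhausts the space", {
  set.seed(25)
  n <- 120
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("x", 1:8)))
  y <- 1.5 * x[, 1] - x[, 3] + rnorm(n, 0, 2)
  e <- enumerate_models(x, y, bma_config(seed = 5))
  m <- mcmc_bas(x, y, bma_config(n_models = 256, seed = 5))
  expect_equal(m$method, "mcmc_bas")
  expect_equal(m$pip, e$pip, tolerance = 1e-12)
  expect_equal(sort(m$posterior_prob), sort(e$posterior_prob), tolerance = 1e-12)
})

test_that("a partial-budget sampler run tracks enumeration inclusion probabilities", {
  set.seed(26)
  n <- 150; p <- 12
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- 1.2 * x[, 1] - 0.8 * x[, 5] + 0.6 * x[, 9] + rnorm(n, 0, 2)
  e <- enumerate_models(x, y, bma_config())
  m <- mcmc_bas(x, y, bma_config(n_models = 1500, seed = 8))
  expect_lt(max(abs(e$pip - m$pip[names(e$pip)])), 0.05)
  # fixed seed: bitwise identical result
  m2 <- mcmc_bas(x, y, bma_config(n_models = 1500, seed = 8))
  expect_identical(m$pip, m2$pip)
  expect_identical(m$log_marginal, m2$log_marginal)
})

test_that("pure-noise designs rarely promote any predictor", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    x <- matrix(rnorm(200 * 8), 200, 8, dimnames = list(NULL, paste0("x", 1:8)))
    e <- enumerate_models(x, rnorm(200), bma_config())
    hits <- hits + all(e$pip < 0.5)
  }
  expect_gte(hits, 35)
})

test_that("the top-model table mirrors the conventional report layout", {
  set.seed(27)
  n <- 100
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 2 + x[, 1] + rnorm(n)
  e <- enumerate_models(x, y, bma_config())
  tab <- top_model_table(e, K = 5)
  expect_equal(tab$bayes_factor[1], 1)
  expect_true(all(diff(tab$posterior_prob) <= 0))
  expect_equal(tab$bayes_factor,
               exp(tab$log_marginal - tab$log_marginal[1]), tolerance = 1e-12)
  one <- top_model_table(e, K = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$posterior_prob, e$posterior_prob[1])
  expect_message(top_model_table(e, K = 100), "truncating")
})

test_that("degenerate inputs are rejected", {
  x <- matrix(numeric(0), 10, 0)
  expect_error(enumerate_models(x, rnorm(10)), "no candidate predictors")
  xb <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("x", 1:5)))
  expect_error(mcmc_bas(xb, rnorm(10), bma_config(n_models = 5)), "at least 10")
  expect_error(enumerate_models(xb, rnorm(10), bma_config(enumeration_limit = 3)),
               "enumeration_limit")
})
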