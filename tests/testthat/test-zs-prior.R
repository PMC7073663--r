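test_that("conditional g-prior Bayes factor matches its closed form", {
  # null vs null: zero for any g
  expect_identical(log_bf_given_g(100, 0, 0.5, 10), 0)
  # no fit, positive dimension: pure penalty, strictly negative
  expect_lt(log_bf_given_g(50, 3, 0, 20), 0)
  # frozen value from independent arithmetic (30-digit evaluation of the
  # two-term formula)
  expect_equal(log_bf_given_g(50, 2, 0.3, 50), 4.60168837684696, tolerance = 1e-12)
  expect_error(log_bf_given_g(50, 2, 1, 10), "saturated")
})

test_that("ZS-null marginal likelihood: null short-circuit, oracle agreement, monotonicity", {
  expect_identical(log_marginal_zs(100, 0, 0.5), 0)
  la <- log_marginal_zs(100, 3, 0.4)
  qu <- log_marginal_zs(100, 3, 0.4, method = "quadrature")
  expect_lt(abs(la - qu), 0.05)
  # increasing R^2 increases the evidence, n and p fixed
  vals <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                 function(r2) log_marginal_zs(120, 4, r2), 0)
  expect_true(all(diff(vals) > 0))
  expect_error(log_marginal_zs(100, 3, 1), "saturated")
})

test_that("Laplace evaluator agrees with adaptive quadrature across regimes", {
  for (n in c(30, 100, 300)) for (p in c(1, 5, 15)) for (r2 in c(0, 0.3, 0.8)) {
    la <- log_marginal_zs(n, p, r2)
    qu <- log_marginal_zs(n, p, r2, method = "quadrature")
    expect_lt(abs(la - qu), 0.05,
              label = sprintf("|laplace - quadrature| at n=%d p=%d r2=%.1f", n, p, r2))
  }
  # the fast scoring path is numerically identical to the public evaluator
  set.seed(1)
  for (i in 1:25) {
    n <- sample(30:300, 1); k <- sample(1:15, 1); r2 <- runif(1, 0, 0.95)
    expect_equal(pairct:::zs_laplace_fast(n, k, r2), log_marginal_zs(n, k, r2),
                 tolerance = 1e-10)
  }
})
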