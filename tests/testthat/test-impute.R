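test_that("a complete table is returned unchanged after zero iterations", {
  tab <- toy_table(n = 10)
  out <- missforest_impute(tab)
  expect_identical(out$table, tab)
  expect_equal(out$diagnostics$iterations, 0L)
})

test_that("constant observed columns are imputed with the constant", {
  tab <- correlated_table(n = 40, seed = 2)
  tab$flat <- 3
  tab$flat[c(5, 9)] <- NA
  tab <- tab[c(setdiff(names(tab), "outcome"), "outcome")]
  expect_warning(out <- missforest_impute(tab, impute_config(n_trees = 20)),
                 "constant")
  expect_equal(out$table$flat[c(5, 9)], c(3, 3))
})

test_that("a covariate with no observed values cannot be imputed", {
  tab <- toy_table(n = 8)
  tab$ghost <- NA_real_
  tab <- tab[c(setdiff(names(tab), "outcome"), "outcome")]
  expect_error(missforest_impute(tab), "no observed values")
})

test_that("observed cells are never altered and categories stay within observed levels", {
  masked <- mask_mcar(correlated_table(n = 120, seed = 4), 0.25, seed = 9)
  out <- missforest_impute(masked$table, impute_config(n_trees = 30, seed = 5))
  for (v in c(paste0("v", 1:6), "cat1")) {
    obs <- which(!is.na(masked$table[[v]]))
    expect_equal(out$table[[v]][obs], masked$table[[v]][obs], info = v)
    expect_false(anyNA(out$table[[v]]))
  }
  imputed_cats <- out$table$cat1[masked$mask$cat1]
  expect_true(all(imputed_cats %in% masked$table$cat1[!is.na(masked$table$cat1)]))
})

test_that("imputation is deterministic under a fixed seed", {
  masked <- mask_mcar(correlated_table(n = 80, seed = 6), 0.2, seed = 3)
  a <- missforest_impute(masked$table, impute_config(n_trees = 30, seed = 42))
  b <- missforest_impute(masked$table, impute_config(n_trees = 30, seed = 42))
  expect_identical(a$table, b$table)
  expect_identical(a$diagnostics$iterations, b$diagnostics$iterations)
})

test_that("random-forest imputation beats mean imputation on correlated covariates", {
  masked <- mask_mcar(correlated_table(n = 150, seed = 8), 0.2, seed = 8)
  out <- missforest_impute(masked$table, impute_config(seed = 8))
  err <- imputation_sq_errors(masked, out, paste0("v", 1:6))
  expect_lt(err[["rf"]], err[["mean"]])
})

test_that("MCAR masking has the right marginal rate and is seed-stable", {
  tab <- correlated_table(n = 200, seed = 10)
  expect_identical(mask_mcar(tab, 0, seed = 1)$table, tab)
  m1 <- mask_mcar(tab, 0.2, seed = 7)
  m2 <- mask_mcar(tab, 0.2, seed = 7)
  expect_identical(m1$table, m2$table)
  n_cells <- 200 * 7
  n_masked <- sum(lengths(m1$mask))
  expect_lt(abs(n_masked / n_cells - 0.2), 3 * sqrt(0.2 * 0.8 / n_cells))
})
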