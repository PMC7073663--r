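test_that("completer filtering removes outcome-missing rows and reports counts", {
  tab <- toy_table(n = 10, n_missing_outcome = 3)
  out <- filter_completers(tab)
  expect_equal(nrow(out$table), 7)
  expect_equal(out$report$removed, 3)
  expect_equal(out$report$retained_tau + out$report$retained_blend, 7)
  # identity on complete tables, and idempotent
  full <- toy_table(n = 8)
  expect_identical(filter_completers(full)$table, full)
  twice <- filter_completers(filter_completers(tab)$table)
  expect_identical(twice$table, out$table)
  expect_equal(twice$report$removed, 0)
})

test_that("an arm with no completers is an error", {
  tab <- toy_table(n = 6)
  tab$outcome[tab$arm == "BLEND"] <- NA
  expect_error(filter_completers(tab), "no completers")
})

test_that("missingness screening applies the strict <50% rule", {
  tab <- toy_table(n = 100)
  tab$mostly_missing <- c(rep(NA_real_, 55), rnorm(45))
  tab$borderline <- c(rep(NA_real_, 49), rnorm(51))
  tab <- tab[c(setdiff(names(tab), "outcome"), "outcome")]
  out <- screen_missingness(tab)
  expect_named(out$dropped, "mostly_missing")
  expect_true("borderline" %in% names(out$table))
  # fully observed table: nothing dropped; idempotent
  expect_length(screen_missingness(out$table)$dropped, 0)
})

test_that("encoding splits nominals into k-1 indicators with deterministic order", {
  n <- 12
  tab <- data.frame(
    patient_id = sprintf("E%02d", 1:n),
    arm = factor(rep(c("TAU", "BLEND"), 6), levels = c("TAU", "BLEND")),
    country = factor(rep(c("Denmark", "France", "Netherlands", "Switzerland"), 3)),
    recurrent = factor(rep(c("no", "yes"), length.out = n)),
    age = seq(20, 64, length.out = n),
    outcome = 5L
  )
  coded <- encode(tab)
  country_cols <- coded$meta$column[coded$meta$source == "country"]
  expect_length(country_cols, 3)
  expect_false("country_Denmark" %in% country_cols)  # reference = first sorted level
  expect_equal(sum(coded$meta$source == "recurrent"), 1)
  expect_true(all(coded$x[, "recurrent"] %in% 0:1))
  expect_true(all(rowSums(coded$x[, country_cols]) <= 1))
  # identical column order for a second table with the same schema
  tab2 <- tab[sample(n), ]
  coded2 <- encode(tab2)
  expect_identical(colnames(coded2$x), colnames(coded$x))
  expect_identical(rownames(coded$x), tab$patient_id)  # row alignment preserved
  # decode reconstructs the labels
  dec <- decode(coded)
  expect_equal(dec$country, as.character(tab$country))
  expect_equal(dec$age, tab$age)
})

test_that("encode requires complete covariates and rejects unseen categories", {
  tab <- toy_table(n = 6)
  tab$severity[2] <- NA
  expect_error(encode(tab), "impute first")

  ref <- encode(toy_table(n = 6))
  new <- toy_table(n = 4)
  levels(new$chronic) <- c("no", "sometimes")
  expect_error(encode(new, meta = ref$meta), "unseen category.*chronic")
})
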