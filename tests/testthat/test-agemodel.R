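test_that("design matrix has 63 documented columns and grouped ages", {
  co <- rand_cohort(18, 5, seed = 1)
  d <- build_design(co$features, co$metadata)
  expect_equal(ncol(d$X), 63)
  expect_equal(nrow(d$X), 90)
  expect_identical(colnames(d$X),
                   c(metric_catalog()$metric, "sex",
                     paste0("sex_x_", metric_catalog()$metric)))
  # replicates inherit the sample age
  ages <- tapply(d$y, d$sample_id, function(v) length(unique(v)))
  expect_true(all(ages == 1))
  # all-female cohort: interaction block identically zero
  cof <- rand_cohort(6, 2, seed = 2)
  cof$metadata$sex <- "F"
  df <- build_design(cof$features, cof$metadata)
  expect_true(all(df$X[, 33:63] == 0))
  # missing metadata and non-finite features are named errors
  expect_error(build_design(co$features,
                            co$metadata[-1, ]), "S001")
  bad <- co$features; bad$AC_2[3] <- NA
  expect_error(build_design(bad, co$metadata), "non-finite")
})

test_that("nested CV has LOO structure with grouped pseudo-replicates", {
  co <- rand_cohort(8, 3, seed = 4)
  d <- build_design(co$features, co$metadata)
  cv <- nested_cv(d, lambda_grid = c(0.3, 3), alpha_grid = c(0.8, 1))
  expect_equal(nrow(cv$folds), 8)                 # one outer fold per sample
  expect_true(all(cv$folds$n_inner_folds == 7))   # LOO inner loop
  expect_equal(ncol(cv$coefs), 8)                 # one estimate set per fold
  # exactly one prediction per pseudo-replicate
  expect_equal(nrow(cv$predictions), 24)
  expect_false(anyDuplicated(cv$predictions[c("sample_id",
                                              "replicate_id")]) > 0)
  expect_setequal(unique(cv$predictions$sample_id), co$metadata$sample_id)
  # chosen hyperparameters come from the grid
  expect_true(all(cv$folds$lambda %in% c(0.3, 3)))
  expect_true(all(cv$folds$alpha %in% c(0.8, 1)))
  expect_error(nested_cv(d, lambda_grid = numeric(0)), "non-empty")
})

test_that("a degenerate one-pair grid reduces to plain LOO at that pair", {
  co <- rand_cohort(6, 2, seed = 8)
  d <- build_design(co$features, co$metadata)
  cv <- nested_cv(d, lambda_grid = 1, alpha_grid = 0.9)
  manual <- lapply(unique(d$sample_id), function(s) {
    test <- d$sample_id == s
    f <- suppressWarnings(fit_enet(d$X[!test, ], d$y[!test], 1, 0.9))
    predict(f, d$X[test, , drop = FALSE])
  })
  expect_equal(cv$predictions$predicted, unlist(manual), tolerance = 1e-12)
})

test_that("performance metrics follow their formulas", {
  fake <- list(predictions = tibble::tibble(
    sample_id = "s", replicate_id = 1:2, age = c(1, 5), predicted = c(2, 4)))
  p <- cohort_performance(fake)
  expect_equal(p$mae, 1); expect_equal(p$mdae, 1); expect_equal(p$rmse, 1)
  expect_equal(p$r, 1)
  exact <- list(predictions = tibble::tibble(
    sample_id = "s", replicate_id = 1:3, age = c(10, 20, 30),
    predicted = c(10, 20, 30)))
  pe <- cohort_performance(exact)
  expect_equal(pe$mae, 0); expect_equal(pe$r, 1); expect_equal(pe$r2, 1)
  # mae <= rmse on random data (Jensen), r in [-1, 1]
  for (seed in 1:5) {
    set.seed(seed)
    fk <- list(predictions = tibble::tibble(
      sample_id = "s", replicate_id = 1:40, age = rnorm(40, 50, 15),
      predicted = rnorm(40, 50, 15)))
    pp <- cohort_performance(fk)
    expect_lte(pp$mae, pp$rmse)
    expect_true(pp$r >= -1 && pp$r <= 1)
  }
  # constant predictions: r undefined -> flagged 0
  cst <- list(predictions = tibble::tibble(
    sample_id = "s", replicate_id = 1:3, age = c(1, 2, 3),
    predicted = c(5, 5, 5)))
  pc <- cohort_performance(cst)
  expect_equal(pc$r, 0); expect_false(pc$r_defined)
})

test_that("age acceleration is the OLS residual of the trend line", {
  cv <- list(predictions = tibble::tibble(
    sample_id = rep(c("a", "b", "c"), each = 2), replicate_id = rep(1:2, 3),
    age = rep(c(20, 40, 60), each = 2),
    predicted = c(25, 27, 40, 42, 55, 57)))
  aa <- age_acceleration(cv)
  expect_equal(mean(aa$age_acceleration), 0, tolerance = 1e-12)
  expect_equal(aa$age_difference, aa$predicted - aa$age)
  # predictions exactly on a line -> zero acceleration everywhere
  online <- list(predictions = tibble::tibble(
    sample_id = letters[1:4], replicate_id = 1, age = c(20, 30, 40, 50),
    predicted = 10 + 0.7 * c(20, 30, 40, 50)))
  expect_equal(age_acceleration(online)$age_acceleration, rep(0, 4),
               tolerance = 1e-12)
  single <- list(predictions = tibble::tibble(
    sample_id = "a", replicate_id = 1:2, age = c(30, 30),
    predicted = c(31, 29)))
  expect_error(age_acceleration(single), "distinct ages")
})

test_that("dummy baseline predicts LOO training means", {
  md <- tibble::tibble(sample_id = c("a", "b", "c"),
                       age = c(20, 40, 60), sex = "F")
  ft <- tibble::tibble(sample_id = c("a", "b", "c"), replicate_id = 1,
                       m1 = rnorm(3))
  d <- build_design(ft, md)
  dm <- dummy_baseline(d)
  expect_equal(dm$predictions$predicted, c(50, 40, 30))
  expect_equal(cohort_performance(dm)$mae, 20)
  same <- build_design(ft, dplyr::mutate(md, age = 33))
  expect_equal(cohort_performance(dummy_baseline(same))$mae, 0)
})

test_that("infinite shrinkage makes nested CV equal the dummy baseline", {
  co <- rand_cohort(6, 2, seed = 10)
  d <- build_design(co$features, co$metadata)
  cv <- nested_cv(d, lambda_grid = 1e9, alpha_grid = 1)
  dm <- dummy_baseline(d)
  expect_equal(cv$predictions$predicted, dm$predictions$predicted,
               tolerance = 1e-10)
})

test_that("external testing trains once and refuses mismatched features", {
  tr <- rand_cohort(8, 2, seed = 12)
  te <- rand_cohort(6, 2, seed = 13)
  dtr <- build_design(tr$features, tr$metadata)
  dte <- build_design(te$features, te$metadata)
  ex <- external_test(dtr, dte, lambda_grid = c(0.3, 3), alpha_grid = 1)
  expect_equal(nrow(ex$predictions), nrow(dte$X))
  expect_gt(cohort_performance(ex)$r, 0)   # shared age signal generalizes
  # self-test sanity: full-train fit at least as accurate as honest CV
  exs <- external_test(dtr, dtr, lambda_grid = c(0.3, 3), alpha_grid = 1)
  cvs <- nested_cv(dtr, lambda_grid = c(0.3, 3), alpha_grid = 1)
  expect_lte(cohort_performance(exs)$mae, cohort_performance(cvs)$mae)
  # feature mismatch is a named error; empty test cohort errors
  bad <- dte; colnames(bad$X)[2] <- "weird_metric"
  expect_error(external_test(dtr, bad), "weird_metric")
  empty <- treeclock:::design_subset(dte, rows = integer(0))
  expect_error(external_test(dtr, empty), "empty")
})

test_that("pre-selection ranks all predictors and k = p is the identity", {
  co <- rand_cohort(6, 2, seed = 21)
  d <- build_design(co$features, co$metadata)
  ps <- preselect_features(d, k_values = c(1, 63), lambda_grid = c(0.3, 3),
                           alpha_grid = 1)
  expect_setequal(ps$ranking, colnames(d$X))
  expect_length(ps$ranking, 63)
  full <- nested_cv(d, lambda_grid = c(0.3, 3), alpha_grid = 1)
  expect_identical(ps$results[["63"]]$predictions$predicted,
                   full$predictions$predicted)
  expect_true(all(c(1, 63) %in% ps$per_k$k))
  expect_error(preselect_features(d, k_values = 99), "\\[1, 63\\]")
})

test_that("marker associations reproduce textbook correlation tests", {
  sp <- tibble::tibble(sample_id = sprintf("S%d", 1:5),
                       cell_tree_age = c(30, 45, 50, 60, 70),
                       age = c(28, 44, 52, 58, 72),
                       sex = c("M", "M", "F", "F", "M"))
  mk <- tibble::tibble(sample_id = sp$sample_id,
                       glucose = c(4.1, 4.8, 5.2, 5.9, 6.5),
                       flat = rep(7, 5))
  res <- marker_associations(sp, mk)
  row <- res[res$marker == "glucose" & res$stratum == "All", ]
  ct <- cor.test(mk$glucose, sp$cell_tree_age)
  expect_equal(row$r_cell_tree_age, unname(ct$estimate))
  expect_equal(row$p_cell_tree_age, ct$p.value)
  # marker equal to chronological age correlates perfectly with it
  mk2 <- tibble::tibble(sample_id = sp$sample_id, shadow = sp$age)
  res2 <- marker_associations(sp, mk2, strata = "All")
  expect_equal(res2$r_chronological, 1)
  # constant marker flagged, small stratum skipped
  expect_match(res$note[res$marker == "flat" & res$stratum == "All"],
               "constant")
  expect_match(res$note[res$marker == "glucose" & res$stratum == "Female"],
               "fewer than 3")
  # manual t-distribution p-value for the hand-sized table
  r <- row$r_cell_tree_age
  tstat <- r * sqrt((5 - 2) / (1 - r^2))
  expect_equal(row$p_cell_tree_age, 2 * stats::pt(-abs(tstat), df = 3),
               tolerance = 1e-12)
})

test_that("sample-level predictions average replicates", {
  cv <- list(predictions = tibble::tibble(
    sample_id = rep(c("a", "b"), each = 2), replicate_id = rep(1:2, 2),
    age = rep(c(30, 50), each = 2), predicted = c(31, 33, 48, 52)))
  md <- tibble::tibble(sample_id = c("a", "b"), age = c(30, 50),
                       sex = c("F", "M"))
  sp <- sample_level_predictions(cv, md)
  expect_equal(sp$cell_tree_age, c(32, 50))
  expect_equal(sp$sex, c("F", "M"))
})
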