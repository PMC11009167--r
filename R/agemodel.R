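#' Build the cohort design matrix
#'
#' Joins a per-replicate feature table to sample metadata and assembles the
#' predictor matrix: the 31 tree statistics, sex (coded F = 0, M = 1), and
#' the 31 sex-by-statistic interaction columns — 63 predictors in a fixed,
#' documented order (`stats`, `sex`, `sex_x_<stat>`). Every pseudo-replicate
#' of a sample carries that sample's chronological age.
#'
#' @param features_table tibble with `sample_id`, `replicate_id` and one
#'   column per tree statistic (e.g. from [compute_feature_table()]).
#' @param metadata tibble with `sample_id`, `age`, `sex` (`"F"`/`"M"`).
#' @return A `cohort_design`: predictor matrix `X`, response `y`,
#'   `sample_id`/`replicate_id` vectors, `stat_names`, and the joined tibble
#'   in `$table`.
#' @export
build_design <- function(features_table, metadata) {
  features_table <- tibble::as_tibble(features_table)
  metadata <- tibble::as_tibble(metadata)
  stopifnot(all(c("sample_id", "replicate_id") %in% names(features_table)),
            all(c("sample_id", "age", "sex") %in% names(metadata)))
  missing_meta <- setdiff(features_table$sample_id, metadata$sample_id)
  if (length(missing_meta))
    tc_abort(paste0("no metadata for sample(s): ",
                    paste(missing_meta, collapse = ", ")), "design")
  if (!all(metadata$sex %in% c("F", "M")))
    tc_abort("sex must be coded 'F'/'M'", "design")
  stat_names <- setdiff(names(features_table), c("sample_id", "replicate_id"))
  tab <- dplyr::inner_join(features_table, metadata, by = "sample_id")
  stats <- as.matrix(tab[stat_names])
  bad <- which(!is.finite(stats), arr.ind = TRUE)
  if (nrow(bad) > 0)
    tc_abort(sprintf("non-finite feature value in row %d (sample %s, %s)",
                     bad[1, 1], tab$sample_id[bad[1, 1]],
                     stat_names[bad[1, 2]]), "design")
  sex_num <- as.numeric(tab$sex == "M")
  inter <- stats * sex_num
  colnames(inter) <- paste0("sex_x_", stat_names)
  X <- cbind(stats, sex = sex_num, inter)
  structure(list(X = X, y = tab$age, sample_id = tab$sample_id,
                 replicate_id = tab$replicate_id, sex = tab$sex,
                 stat_names = stat_names, table = tab),
            class = "cohort_design")
}

#' @exportS3Method base::print
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", length(unique(x$sample_id)), " samples, ",
      nrow(x$X), " pseudo-replicates, ", ncol(x$X), " predictors\n", sep = "")
  invisible(x)
}

# subset a design's rows (samples) or columns (predictors)
design_subset <- function(d, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(d$X))
  cols <- cols %||% seq_len(ncol(d$X))
  structure(list(X = d$X[rows, cols, drop = FALSE], y = d$y[rows],
                 sample_id = d$sample_id[rows],
                 replicate_id = d$replicate_id[rows], sex = d$sex[rows],
                 stat_names = d$stat_names,
                 table = d$table[rows, , drop = FALSE]),
            class = "cohort_design")
}

# one (lambda, alpha) selection by leave-one-sample-out CV on a design;
# returns the best grid pair (ties -> first in grid order, lambda fastest)
select_hyperparams <- function(d, lambda_grid, alpha_grid, standardize, tol) {
  grid <- expand.grid(lambda = lambda_grid, alpha = alpha_grid,
                      KEEP.OUT.ATTRS = FALSE)
  ids <- unique(d$sample_id)
  err_sum <- numeric(nrow(grid)); err_n <- 0L
  for (s in ids) {
    test <- d$sample_id == s
    Xtr <- d$X[!test, , drop = FALSE]; ytr <- d$y[!test]
    Xte <- d$X[test, , drop = FALSE];  yte <- d$y[test]
    warm <- NULL
    for (g in seq_len(nrow(grid))) {
      fit <- suppressWarnings(
        fit_enet(Xtr, ytr, grid$lambda[g], grid$alpha[g],
                 standardize = standardize, tol = tol, beta_init = warm))
      warm <- fit$beta
      err_sum[g] <- err_sum[g] + sum(abs(predict(fit, Xte) - yte))
    }
    err_n <- err_n + sum(test)
  }
  best <- which.min(err_sum / err_n)
  list(lambda = grid$lambda[best], alpha = grid$alpha[best],
       inner_mae = err_sum[best] / err_n, n_inner_folds = length(ids))
}

#' Nested leave-one-out cross-validation of the age model
#'
#' Outer loop: each sample (with all of its pseudo-replicates) is held out
#' once. Inner loop: leave-one-sample-out CV on the remaining samples scores
#' every (lambda, alpha) pair of the exhaustive grid by mean absolute error
#' over held-out replicates; the best pair refits on the full outer training
#' set and predicts the held-out replicates. Pseudo-replicates of one sample
#' are never split across training and test, and every pseudo-replicate
#' receives exactly one prediction. Each coefficient vector is estimated once
#' per outer fold.
#'
#' @param design a [build_design()] cohort.
#' @param lambda_grid,alpha_grid hyperparameter grids; defaults are
#'   `{0.1, 0.3, 1, 3, 10}` and `{0.6, 0.7, 0.8, 0.9, 1}`.
#' @param standardize passed to [fit_enet()].
#' @param tol coordinate-descent tolerance.
#' @return A `tc_cv`: `predictions` (tibble sample_id, replicate_id, age,
#'   predicted), `folds` (chosen hyperparameters per outer fold), `coefs`
#'   (fitting-scale coefficients, predictors x folds).
#' @export
nested_cv <- function(design, lambda_grid = c(0.1, 0.3, 1, 3, 10),
                      alpha_grid = c(0.6, 0.7, 0.8, 0.9, 1),
                      standardize = TRUE, tol = 1e-6) {
  stopifnot(inherits(design, "cohort_design"))
  if (length(lambda_grid) == 0 || length(alpha_grid) == 0)
    tc_abort("hyperparameter grids must be non-empty", "cv")
  ids <- unique(design$sample_id)
  if (length(ids) < 3) tc_abort("need at least 3 samples", "cv")
  preds <- vector("list", length(ids))
  folds <- vector("list", length(ids))
  coefs <- matrix(NA_real_, ncol(design$X), length(ids),
                  dimnames = list(colnames(design$X), ids))
  for (f in seq_along(ids)) {
    s <- ids[f]
    test <- design$sample_id == s
    train_d <- design_subset(design, rows = which(!test))
    stopifnot(!s %in% train_d$sample_id)  # group integrity
    hp <- select_hyperparams(train_d, lambda_grid, alpha_grid,
                             standardize, tol)
    fit <- suppressWarnings(
      fit_enet(train_d$X, train_d$y, hp$lambda, hp$alpha,
               standardize = standardize, tol = tol))
    coefs[, f] <- fit$beta
    yhat <- predict(fit, design$X[test, , drop = FALSE])
    preds[[f]] <- tibble::tibble(sample_id = design$sample_id[test],
                                 replicate_id = design$replicate_id[test],
                                 age = design$y[test], predicted = yhat)
    folds[[f]] <- tibble::tibble(fold = s, lambda = hp$lambda,
                                 alpha = hp$alpha, inner_mae = hp$inner_mae,
                                 n_inner_folds = hp$n_inner_folds)
  }
  structure(list(predictions = dplyr::bind_rows(preds),
                 folds = dplyr::bind_rows(folds), coefs = coefs,
                 lambda_grid = lambda_grid, alpha_grid = alpha_grid,
                 standardize = standardize, method = "nested_cv"),
            class = "tc_cv")
}

#' Prediction performance of a cross-validated model
#'
#' Mean absolute error, median absolute error, root-mean-squared error,
#' Pearson correlation and its square, over all (predicted, chronological)
#' age pairs. Zero-variance predictions make r undefined; it is reported as
#' 0 with `r_defined = FALSE`.
#'
#' @param cv a `tc_cv` (or anything with a `$predictions` tibble holding
#'   `age` and `predicted`).
#' @return One-row tibble: `mae`, `mdae`, `rmse`, `r`, `r2`, `n`,
#'   `r_defined`.
#' @export
cohort_performance <- function(cv) {
  p <- cv$predictions
  stopifnot(all(c("age", "predicted") %in% names(p)))
  err <- p$predicted - p$age
  r_def <- stats::sd(p$predicted) > 0 && stats::sd(p$age) > 0
  r <- if (r_def) cor(p$predicted, p$age) else 0
  tibble::tibble(mae = mean(abs(err)), mdae = median(abs(err)),
                 rmse = sqrt(mean(err^2)), r = r, r2 = r^2,
                 n = nrow(p), r_defined = r_def)
}

#' @export
glance.tc_cv <- function(x, ...) cohort_performance(x)

#' @export
tidy.tc_cv <- function(x, ...) {
  if (is.null(x$coefs)) return(tibble::tibble())
  tibble::as_tibble(x$coefs, rownames = "term") |>
    tidyr::pivot_longer(-"term", names_to = "fold", values_to = "estimate")
}

#' @exportS3Method base::print
print.tc_cv <- function(x, ...) {
  perf <- cohort_performance(x)
  cat("<tc_cv:", x$method, "> ", length(unique(x$predictions$sample_id)),
      " samples, ", nrow(x$predictions), " predictions\n", sep = "")
  cat(sprintf("  mae=%.3f mdae=%.3f rmse=%.3f r=%.3f\n",
              perf$mae, perf$mdae, perf$rmse, perf$r))
  invisible(x)
}

#' Age difference and age acceleration
#'
#' Age difference is predicted minus chronological age. Age acceleration is
#' the residual of the predicted age from the ordinary least-squares trend
#' line of predicted on chronological age over all replicates — the
#' customary correction for the regression-to-the-mean bias of penalized
#' clocks (fitted slope below 1: young overestimated, old underestimated).
#'
#' @param cv a `tc_cv`.
#' @return The predictions tibble augmented with `age_difference` and
#'   `age_acceleration`; the trend line is in attributes `intercept`/`slope`.
#' @export
age_acceleration <- function(cv) {
  p <- cv$predictions
  if (length(unique(p$age)) < 2)
    tc_abort("need at least two distinct ages for a trend line", "accel")
  fit <- lm(predicted ~ age, data = p)
  out <- dplyr::mutate(p,
    age_difference = .data$predicted - .data$age,
    age_acceleration = .data$predicted - unname(stats::fitted(fit)))
  attr(out, "intercept") <- unname(coef(fit)[1])
  attr(out, "slope") <- unname(coef(fit)[2])
  out
}

#' Dummy regressor baseline
#'
#' Leave-one-sample-out baseline that ignores the tree metrics entirely: in
#' each fold the training-set mean age is predicted for all held-out
#' replicates. Equals the elastic net in the infinite-shrinkage limit.
#'
#' @param design a [build_design()] cohort.
#' @return A `tc_cv` with `method = "dummy"`.
#' @export
dummy_baseline <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  ids <- unique(design$sample_id)
  if (length(ids) < 2) tc_abort("need at least 2 samples", "cv")
  preds <- lapply(ids, function(s) {
    test <- design$sample_id == s
    tibble::tibble(sample_id = design$sample_id[test],
                   replicate_id = design$replicate_id[test],
                   age = design$y[test],
                   predicted = mean(design$y[!test]))
  })
  structure(list(predictions = dplyr::bind_rows(preds),
                 folds = tibble::tibble(fold = ids), coefs = NULL,
                 method = "dummy"), class = "tc_cv")
}

#' Train on one cohort, test on an external cohort
#'
#' One step of the outer loop at cohort scale: hyperparameters are selected
#' by leave-one-sample-out CV inside the training cohort, the model is refit
#' on all training rows, and every test-cohort replicate is predicted.
#'
#' @param train,test [build_design()] cohorts with identical predictor sets.
#' @param lambda_grid,alpha_grid hyperparameter grids.
#' @param standardize,tol passed to [fit_enet()].
#' @return A `tc_cv` with `method = "external"`, plus the chosen
#'   hyperparameters and final `fit`.
#' @export
external_test <- function(train, test, lambda_grid = c(0.1, 0.3, 1, 3, 10),
                          alpha_grid = c(0.6, 0.7, 0.8, 0.9, 1),
                          standardize = TRUE, tol = 1e-6) {
  stopifnot(inherits(train, "cohort_design"), inherits(test, "cohort_design"))
  if (nrow(test$X) == 0) tc_abort("test cohort is empty", "external")
  if (!identical(colnames(train$X), colnames(test$X)))
    tc_abort(paste0("predictor mismatch: ",
                    paste(union(setdiff(colnames(train$X), colnames(test$X)),
                                setdiff(colnames(test$X), colnames(train$X))),
                          collapse = ", ")), "external")
  hp <- select_hyperparams(train, lambda_grid, alpha_grid, standardize, tol)
  fit <- suppressWarnings(
    fit_enet(train$X, train$y, hp$lambda, hp$alpha,
             standardize = standardize, tol = tol))
  yhat <- predict(fit, test$X)
  structure(list(predictions = tibble::tibble(
    sample_id = test$sample_id, replicate_id = test$replicate_id,
    age = test$y, predicted = yhat),
    folds = tibble::tibble(fold = "external", lambda = hp$lambda,
                           alpha = hp$alpha, inner_mae = hp$inner_mae),
    coefs = matrix(fit$beta, ncol = 1,
                   dimnames = list(names(fit$beta), "external")),
    fit = fit, method = "external"), class = "tc_cv")
}

#' Feature pre-selection by coefficient magnitude
#'
#' Two-step adaptive scheme: a first nested CV on all predictors ranks
#' features by the mean absolute fitting-scale coefficient across outer-fold
#' estimates (ties broken by design column order); then nested CV is rerun
#' using only the top-k ranked predictors for each requested `k`, and the k
#' minimizing MAE is reported. `k` is deliberately not tuned in the inner
#' loop. Column order of the original design is preserved within each
#' subset, so `k = ncol(X)` reproduces the all-features model exactly.
#'
#' @param design a [build_design()] cohort.
#' @param k_values integer vector of feature counts to evaluate.
#' @param lambda_grid,alpha_grid,standardize,tol as in [nested_cv()].
#' @return A `tc_preselect` list: `ranking` (all predictors, best first),
#'   `per_k` (tibble of k and performance), `results` (named list of
#'   `tc_cv`), `best_k`, `full` (the ranking-step `tc_cv`).
#' @export
preselect_features <- function(design, k_values,
                               lambda_grid = c(0.1, 0.3, 1, 3, 10),
                               alpha_grid = c(0.6, 0.7, 0.8, 0.9, 1),
                               standardize = TRUE, tol = 1e-6) {
  stopifnot(inherits(design, "cohort_design"))
  p <- ncol(design$X)
  k_values <- as.integer(k_values)
  if (any(k_values < 1 | k_values > p))
    tc_abort(sprintf("k_values must lie in [1, %d]", p), "preselect")
  full <- nested_cv(design, lambda_grid, alpha_grid, standardize, tol)
  magnitude <- rowMeans(abs(full$coefs))
  ranking <- order(-magnitude, seq_len(p))   # ties: fixed column order
  ranked_names <- colnames(design$X)[ranking]
  results <- list(); per_k <- list()
  for (k in k_values) {
    cols <- sort(ranking[seq_len(k)])        # preserve design column order
    cvk <- nested_cv(design_subset(design, cols = cols),
                     lambda_grid, alpha_grid, standardize, tol)
    results[[as.character(k)]] <- cvk
    per_k[[as.character(k)]] <-
      dplyr::bind_cols(tibble::tibble(k = k), cohort_performance(cvk))
  }
  per_k <- dplyr::bind_rows(per_k)
  structure(list(ranking = ranked_names, per_k = per_k, results = results,
                 best_k = per_k$k[which.min(per_k$mae)], full = full),
            class = "tc_preselect")
}

#' @exportS3Method base::print
print.tc_preselect <- function(x, ...) {
  cat("<tc_preselect> best k =", x$best_k, "\n")
  print(x$per_k)
  invisible(x)
}

#' Associations between cell tree age and clinical markers
#'
#' Pearson correlation (with two-sided t-distribution p-values) of each
#' numeric marker against the per-sample mean cell tree age and against
#' chronological age, within strata All / Male / Female. Asterisk-style
#' significance is flagged at p < 0.05 without multiple-testing correction.
#' Strata or markers with fewer than 3 complete pairs, or with zero
#' variance, are skipped with a note.
#'
#' @param sample_predictions tibble with `sample_id`, `cell_tree_age`, `age`,
#'   `sex` — e.g. from [sample_level_predictions()].
#' @param markers tibble with `sample_id` and numeric marker columns.
#' @param strata subset of `c("All", "Male", "Female")`.
#' @return Tibble: marker, stratum, n, r/p/significance against cell tree
#'   age and against chronological age, and a `note` column.
#' @export
marker_associations <- function(sample_predictions, markers,
                                strata = c("All", "Male", "Female")) {
  sp <- dplyr::inner_join(tibble::as_tibble(sample_predictions),
                          tibble::as_tibble(markers), by = "sample_id")
  marker_names <- setdiff(names(markers), "sample_id")
  out <- list()
  for (st in strata) {
    rows <- switch(st, All = rep(TRUE, nrow(sp)), Male = sp$sex == "M",
                   Female = sp$sex == "F")
    dat <- sp[rows, , drop = FALSE]
    for (mk in marker_names) {
      x <- dat[[mk]]
      ok <- complete.cases(x, dat$cell_tree_age, dat$age)
      if (sum(ok) < 3) {
        out[[length(out) + 1L]] <- tibble::tibble(
          marker = mk, stratum = st, n = sum(ok), r_cell_tree_age = NA_real_,
          p_cell_tree_age = NA_real_, sig_cell_tree_age = NA,
          r_chronological = NA_real_, p_chronological = NA_real_,
          sig_chronological = NA, note = "fewer than 3 pairs; skipped")
        next
      }
      xo <- x[ok]
      if (stats::sd(xo) == 0) {
        out[[length(out) + 1L]] <- tibble::tibble(
          marker = mk, stratum = st, n = sum(ok), r_cell_tree_age = NA_real_,
          p_cell_tree_age = NA_real_, sig_cell_tree_age = NA,
          r_chronological = NA_real_, p_chronological = NA_real_,
          sig_chronological = NA, note = "constant marker; skipped")
        next
      }
      ct1 <- stats::cor.test(xo, dat$cell_tree_age[ok])
      ct2 <- stats::cor.test(xo, dat$age[ok])
      out[[length(out) + 1L]] <- tibble::tibble(
        marker = mk, stratum = st, n = sum(ok),
        r_cell_tree_age = unname(ct1$estimate),
        p_cell_tree_age = ct1$p.value,
        sig_cell_tree_age = ct1$p.value < 0.05,
        r_chronological = unname(ct2$estimate),
        p_chronological = ct2$p.value,
        sig_chronological = ct2$p.value < 0.05, note = NA_character_)
    }
  }
  dplyr::bind_rows(out)
}

#' Per-sample mean cell tree age
#'
#' Averages replicate-level predictions to one cell tree age per sample and
#' attaches chronological age and sex.
#'
#' @param cv a `tc_cv`.
#' @param metadata tibble with `sample_id`, `sex` (and optionally more).
#' @return Tibble: `sample_id`, `cell_tree_age`, `age`, `sex`.
#' @export
sample_level_predictions <- function(cv, metadata) {
  cv$predictions |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(cell_tree_age = mean(.data$predicted),
                     age = .data$age[1], .groups = "drop") |>
    dplyr::left_join(dplyr::select(tibble::as_tibble(metadata),
                                   "sample_id", "sex"), by = "sample_id")
}
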