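fast_grid <- hyper_grid(
  svm_c = c(1, 5), svm_kernel = c("linear", "radial"),
  mlp_alpha = 0.001, mlp_maxit = 120, rf_ntree = 150
)

test_that("all three algorithms are perfect on a widely separable table", {
  tab <- separable_table(n_per = 15, sep = 10)
  for (alg in c("rf", "svm", "mlp")) {
    cv <- cv_classify(tab, alg, seed = 2, grid = fast_grid, importance = FALSE)
    expect_equal(cv$mean_f1, 1, info = alg)
    expect_equal(cv$mean_accuracy, 1, info = alg)
  }
})

test_that("cross-validation is deterministic given the seed", {
  tab <- separable_table(n_per = 10, sep = 1.5, seed = 8)
  a <- cv_classify(tab, "rf", seed = 5, grid = fast_grid)
  b <- cv_classify(tab, "rf", seed = 5, grid = fast_grid)
  expect_equal(a$folds, b$folds)
  expect_equal(a$importance, b$importance)
  c_ <- cv_classify(tab, "rf", seed = 6, grid = fast_grid)
  expect_false(identical(a$folds$f1, c_$folds$f1))
})

test_that("mean F1 is the arithmetic mean over the five folds", {
  tab <- separable_table(n_per = 12, sep = 1, seed = 3)
  cv <- cv_classify(tab, "svm", seed = 4, grid = fast_grid, importance = FALSE)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(cv$mean_f1, mean(cv$folds$f1))
  expect_equal(cv$mean_accuracy, mean(cv$folds$accuracy))
  fold_sizes <- as.integer(table(stratified_folds(tab$group, 5,
    seed = pointback:::derive_seed(4, 1)
  ))[as.character(1:5)])
  expect_equal(cv$folds$tp + cv$folds$fp + cv$folds$fn + cv$folds$tn, fold_sizes)
})

test_that("permuted labels score inside the permutation-null band", {
  tab <- separable_table(n_per = 14, sep = 4, seed = 11)
  stat <- function(t, s) {
    cv_classify(t, "svm",
      seed = s, grid = fast_grid, nested = FALSE,
      importance = FALSE
    )$mean_f1
  }
  null <- permutation_null(tab, stat, n_perm = 30, seed = 21)
  # a permuted copy of the table is itself a draw from the null
  set.seed(99)
  tab_p <- tab
  tab_p$group <- sample(tab_p$group)
  obs <- stat(tab_p, 7)
  expect_gte(obs, min(null) - 0.15)
  expect_lte(obs, max(null) + 0.15)
  # while the intact separable table is far above the whole band
  expect_gt(stat(tab, 7), max(null))
})

test_that("importances are normalised and concentrate on the signal feature", {
  set.seed(6)
  n_per <- 15
  tab <- tibble::tibble(
    group = rep(c("e33", "e34"), each = n_per),
    signal = c(stats::rnorm(n_per, 0), stats::rnorm(n_per, 4)),
    noise1 = stats::rnorm(2 * n_per),
    noise2 = stats::rnorm(2 * n_per),
    noise3 = stats::rnorm(2 * n_per)
  )
  for (alg in c("rf", "svm", "mlp")) {
    cv <- cv_classify(tab, alg, seed = 3, grid = fast_grid)
    expect_equal(sum(cv$importance), 1, tolerance = 1e-9, info = alg)
    expect_true(all(cv$importance >= 0), info = alg)
    expect_equal(names(which.max(cv$importance)), "signal", info = alg)
  }
})

test_that("pure-noise tables spread importance near uniformly", {
  f1_shares <- c()
  for (s in 1:3) {
    set.seed(100 + s)
    tab <- tibble::tibble(
      group = rep(c("e33", "e34"), each = 14),
      a = stats::rnorm(28), b = stats::rnorm(28),
      c = stats::rnorm(28), d = stats::rnorm(28), e = stats::rnorm(28)
    )
    cv <- cv_classify(tab, "rf", seed = s, grid = fast_grid)
    f1_shares <- c(f1_shares, max(cv$importance))
  }
  # no feature should dominate: below 3x the uniform share of 1/5
  expect_true(all(f1_shares < 3 / 5))
})

test_that("training-side statistics never see held-out fold data", {
  tab <- separable_table(n_per = 12, sep = 2, seed = 13)
  base <- cv_classify(tab, "svm", seed = 9, grid = fast_grid, importance = FALSE)
  folds <- stratified_folds(tab$group, 5, seed = pointback:::derive_seed(9, 1))
  for (f in 1:5) {
    poisoned <- tab
    num <- names(tab)[vapply(tab, is.numeric, logical(1))]
    poisoned[folds == f, num] <- 1e6 # sentinel values in the held-out fold
    cv_p <- cv_classify(poisoned, "svm",
      seed = 9, grid = fast_grid,
      importance = FALSE
    )
    expect_equal(cv_p$folds$scaling[[f]], base$folds$scaling[[f]])
    expect_equal(cv_p$folds$params[[f]], base$folds$params[[f]])
  }
})

test_that("the trial sweep reports every cell with best flags per metric", {
  co <- generate_cohort(small_config(effect_size = 2, seed = 23))
  ft <- extract_feature_table(co)
  ft <- ft[ft$trial_id %in% 1:2, ]
  res <- classify_trials(ft,
    feature_sets = c("all", "no_end_error"),
    seed = 3, grid = fast_grid, nested = FALSE, importance = FALSE, k = 3
  )
  expect_s3_class(res, "vrt_summary")
  expect_equal(nrow(res), 2 * 2 * 3)
  counts <- dplyr::count(res, trial_id, feature_set)
  expect_true(all(counts$n == 3))
  flags <- res |>
    dplyr::group_by(trial_id, feature_set) |>
    dplyr::summarise(n_f1 = sum(best_f1), n_acc = sum(best_accuracy), .groups = "drop")
  expect_true(all(flags$n_f1 >= 1 & flags$n_acc >= 1))
  # feature sets really differ in their design columns
  tab_all <- pointback:::feature_set_columns(ft, "all")
  expect_true("end_error" %in% names(tab_all))
  expect_false("end_error" %in% names(pointback:::feature_set_columns(ft, "no_end_error")))
  expect_false(any(c("age", "sex") %in%
    names(pointback:::feature_set_columns(ft, "no_demographics"))))
})

test_that("tidy, glance and plots expose the fitted results", {
  tab <- separable_table(n_per = 10, sep = 3, seed = 5)
  cv <- cv_classify(tab, "rf", seed = 2, grid = fast_grid)
  td <- tidy(cv)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  gl <- glance(cv)
  expect_equal(gl$mean_f1, cv$mean_f1)
  it <- importance_table(cv)
  expect_equal(sum(it$importance), 1, tolerance = 1e-9)

  co <- generate_cohort(small_config(seed = 31))
  ft <- extract_feature_table(co)
  res <- classify_trials(ft[ft$trial_id == 1, ],
    feature_sets = "all",
    seed = 1, grid = fast_grid, nested = FALSE, k = 3
  )
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_importance(res), "ggplot")
  expect_s3_class(plot_stream(co$trials$stream[[1]]), "ggplot")
})
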