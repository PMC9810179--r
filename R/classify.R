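#' Hyperparameter grids for the three classifiers
#'
#' The grids searched per training fold: SVM regularisation
#' `C in {0.5, 1, 3, 5, 10, 20}` over linear and radial-basis kernels, and
#' MLP weight-decay `alpha in {0.0001, 0.0005, 0.001, 0.002}`. The random
#' forest uses standard defaults (no grid). `mlp_size` and `mlp_maxit`
#' fix the single hidden layer of the perceptron; `rf_ntree` the forest
#' size.
#'
#' @param svm_c,svm_kernel,mlp_alpha Grid values.
#' @param mlp_size Hidden units of the MLP.
#' @param mlp_maxit Training iterations of the MLP.
#' @param rf_ntree Trees in the random forest.
#' @return A list of class `vrt_grid`.
#' @export
hyper_grid <- function(svm_c = c(0.5, 1, 3, 5, 10, 20),
                       svm_kernel = c("linear", "radial"),
                       mlp_alpha = c(0.0001, 0.0005, 0.001, 0.002),
                       mlp_size = 5, mlp_maxit = 200, rf_ntree = 500) {
  structure(
    list(
      svm_c = svm_c, svm_kernel = svm_kernel, mlp_alpha = mlp_alpha,
      mlp_size = mlp_size, mlp_maxit = mlp_maxit, rf_ntree = rf_ntree
    ),
    class = "vrt_grid"
  )
}

# bounded deterministic seed derivation (all RNG flows from one master seed)
derive_seed <- function(seed, a = 0L, b = 0L) {
  as.integer((as.numeric(seed) * 7919 + a * 104729 + b * 131) %% 2147483629)
}

# one-hot encode factors/characters against the full table's level sets so
# every fold sees the same design-matrix schema
build_design <- function(table, positive = "e34") {
  drop_cols <- intersect(c("participant_id", "trial_id", "group"), names(table))
  y <- factor(table$group, levels = c(setdiff(sort(unique(table$group)), positive), positive))
  feats <- table[setdiff(names(table), drop_cols)]
  cols <- list()
  for (nm in names(feats)) {
    v <- feats[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      lv <- sort(unique(as.character(v)))
      for (l in lv) cols[[paste0(nm, "_", l)]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in feature table")
  list(X = X, y = y)
}

scale_fit <- function(X_train) {
  mu <- colMeans(X_train)
  sd <- apply(X_train, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

scale_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")
}

param_grid_for <- function(algorithm, grid) {
  switch(algorithm,
    rf = list(list()),
    svm = {
      g <- expand.grid(
        kernel = grid$svm_kernel, cost = grid$svm_c,
        stringsAsFactors = FALSE
      )
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    mlp = lapply(grid$mlp_alpha, function(a) list(alpha = a)),
    stop("unknown algorithm: ", algorithm)
  )
}

fit_model <- function(algorithm, X, y, params, grid, seed) {
  set.seed(seed)
  if (algorithm == "rf") {
    model <- randomForest::randomForest(x = X, y = y, ntree = grid$rf_ntree)
    list(
      predict = function(newX) stats::predict(model, newX),
      importance = model$importance[, "MeanDecreaseGini"]
    )
  } else if (algorithm == "svm") {
    model <- e1071::svm(
      x = X, y = y, kernel = params$kernel, cost = params$cost, scale = FALSE
    )
    list(predict = function(newX) stats::predict(model, newX), importance = NULL)
  } else if (algorithm == "mlp") {
    df <- data.frame(X, check.names = FALSE)
    df$.y <- y
    model <- nnet::nnet(.y ~ .,
      data = df, size = grid$mlp_size, decay = params$alpha,
      maxit = grid$mlp_maxit, trace = FALSE
    )
    list(
      predict = function(newX) {
        p <- stats::predict(model, data.frame(newX, check.names = FALSE))
        factor(levels(y)[1 + (p[, 1] > 0.5)], levels = levels(y))
      },
      importance = NULL
    )
  } else {
    stop("unknown algorithm: ", algorithm)
  }
}

fold_f1 <- function(truth, pred, positive, average) {
  cc <- confusion_counts(truth, pred, positive)
  if (average == "weighted") {
    f1_weighted(cc$tp, cc$fp, cc$fn, cc$tn)
  } else {
    f1_score(cc$tp, cc$fp, cc$fn, cc$tn)
  }
}

select_params <- function(algorithm, X_train, y_train, grid, nested, inner_k,
                          seed, positive, average) {
  params_list <- param_grid_for(algorithm, grid)
  if (length(params_list) == 1) {
    return(params_list[[1]])
  }
  scores <- if (nested) {
    inner <- stratified_folds(y_train, k = inner_k, seed = derive_seed(seed, 7))
    vapply(seq_along(params_list), function(pi) {
      mean(vapply(seq_len(inner_k), function(f) {
        tr <- inner != f
        sc <- scale_fit(X_train[tr, , drop = FALSE])
        m <- fit_model(
          algorithm, scale_apply(X_train[tr, , drop = FALSE], sc),
          y_train[tr], params_list[[pi]], grid, derive_seed(seed, pi, f)
        )
        pred <- m$predict(scale_apply(X_train[!tr, , drop = FALSE], sc))
        suppressWarnings(fold_f1(y_train[!tr], pred, positive, average))
      }, numeric(1)))
    }, numeric(1))
  } else {
    # naive mode: score each grid point by resubstitution on the training
    # portion (single un-nested grid search, for comparison with nesting)
    sc <- scale_fit(X_train)
    Xs <- scale_apply(X_train, sc)
    vapply(seq_along(params_list), function(pi) {
      m <- fit_model(algorithm, Xs, y_train, params_list[[pi]], grid,
                     derive_seed(seed, pi))
      suppressWarnings(fold_f1(y_train, m$predict(Xs), positive, average))
    }, numeric(1))
  }
  params_list[[which.max(scores)]] # ties resolve to the first grid point
}

permutation_importance <- function(model, X_test, y_test, positive, average,
                                   n_perm, seed) {
  base <- suppressWarnings(fold_f1(y_test, model$predict(X_test), positive, average))
  set.seed(seed)
  vapply(seq_len(ncol(X_test)), function(j) {
    drops <- vapply(seq_len(n_perm), function(p) {
      Xp <- X_test
      Xp[, j] <- Xp[sample(nrow(Xp)), j]
      base - suppressWarnings(fold_f1(y_test, model$predict(Xp), positive, average))
    }, numeric(1))
    mean(drops)
  }, numeric(1))
}

#' Cross-validated classification of genotype group for one trial
#'
#' Stratified five-fold cross-validation of one per-trial feature table
#' with one of the three algorithms. Within each training fold,
#' hyperparameters are chosen by grid search (by default nested: an inner
#' stratified 3-fold on the training portion only), features are
#' standardised with training-fold statistics only, the model is refit on
#' the whole training portion, and the held-out fold yields confusion
#' counts, F1 and accuracy. Fold F1 scores are averaged arithmetically.
#'
#' Feature importances are normalised to sum to 1: the random forest
#' reports impurity (mean decrease in Gini) importances; the SVM and MLP
#' report permutation importances measured on the held-out folds.
#'
#' @param table Feature table for one trial: a `group` label column
#'   (e33/e34) plus numeric/categorical predictor columns.
#'   `participant_id` and `trial_id` columns are ignored if present.
#' @param algorithm `"rf"`, `"svm"` or `"mlp"`.
#' @param k Outer folds (default 5).
#' @param seed Master seed; every stochastic component consumes a seed
#'   derived from it.
#' @param grid A [hyper_grid()].
#' @param nested Nested grid search (default `TRUE`); `FALSE` gives a
#'   single un-nested search scored by training-set resubstitution.
#' @param inner_k Inner folds for the nested search.
#' @param positive Positive class for F1 (default the e3e4 risk group).
#' @param f1_average `"binary"` (positive-class F1) or `"weighted"`
#'   (prevalence-weighted mean of both classes' F1).
#' @param importance Compute feature importances (default `TRUE`; disable
#'   in large permutation loops for speed).
#' @param n_perm Permutations per feature for permutation importance.
#' @return An object of class `vrt_cv`: list with `folds` (per-fold
#'   tibble: confusion counts, `f1`, `accuracy`, chosen `params`, scaling
#'   statistics), `mean_f1`, `mean_accuracy`, `importance` (named vector
#'   summing to 1, or `NULL`), and metadata.
#' @export
cv_classify <- function(table, algorithm = c("rf", "svm", "mlp"), k = 5,
                        seed = 1L, grid = hyper_grid(), nested = TRUE,
                        inner_k = 3, positive = "e34",
                        f1_average = c("binary", "weighted"),
                        importance = TRUE, n_perm = 5) {
  algorithm <- match.arg(algorithm)
  f1_average <- match.arg(f1_average)
  if (anyNA(table$group)) stop("missing group labels")
  d <- build_design(table, positive = positive)
  folds <- stratified_folds(d$y, k = k, seed = derive_seed(seed, 1))

  imp_sum <- numeric(ncol(d$X))
  fold_rows <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- folds != f
    X_tr <- d$X[tr, , drop = FALSE]
    y_tr <- d$y[tr]
    params <- select_params(
      algorithm, X_tr, y_tr, grid, nested, inner_k,
      derive_seed(seed, 2, f), positive, f1_average
    )
    sc <- scale_fit(X_tr)
    model <- fit_model(
      algorithm, scale_apply(X_tr, sc), y_tr, params, grid,
      derive_seed(seed, 3, f)
    )
    X_te <- scale_apply(d$X[!tr, , drop = FALSE], sc)
    pred <- model$predict(X_te)
    cc <- confusion_counts(d$y[!tr], pred, positive)

    if (importance) {
      fi <- if (algorithm == "rf") {
        model$importance
      } else {
        permutation_importance(
          model, X_te, d$y[!tr], positive, f1_average,
          n_perm, derive_seed(seed, 4, f)
        )
      }
      imp_sum <<- imp_sum + fi
    }

    dplyr::bind_cols(
      tibble::tibble(fold = f),
      cc,
      tibble::tibble(
        f1 = suppressWarnings(
          if (f1_average == "weighted") f1_weighted(cc$tp, cc$fp, cc$fn, cc$tn)
          else f1_score(cc$tp, cc$fp, cc$fn, cc$tn)
        ),
        accuracy = accuracy_score(cc$tp, cc$fp, cc$fn, cc$tn),
        params = list(params),
        scaling = list(sc)
      )
    )
  })

  imp <- NULL
  if (importance) {
    imp <- pmax(imp_sum / k, 0)
    if (sum(imp) == 0) {
      warning("all importances are zero; returning uniform scores")
      imp <- rep(1, length(imp))
    }
    imp <- imp / sum(imp)
    names(imp) <- colnames(d$X)
  }

  structure(
    list(
      algorithm = algorithm, k = k, seed = seed, nested = nested,
      positive = positive, f1_average = f1_average,
      folds = fold_rows,
      mean_f1 = mean(fold_rows$f1),
      mean_accuracy = mean(fold_rows$accuracy),
      importance = imp,
      feature_names = colnames(d$X)
    ),
    class = "vrt_cv"
  )
}

#' @export
print.vrt_cv <- function(x, ...) {
  cat(
    "<vrt_cv> ", toupper(x$algorithm), ", ", x$k, "-fold stratified CV\n",
    "  mean F1: ", round(x$mean_f1, 3),
    "   mean accuracy: ", round(x$mean_accuracy, 3), "\n",
    sep = ""
  )
  invisible(x)
}

feature_set_columns <- function(table, feature_set) {
  switch(feature_set,
    all = table,
    no_end_error = dplyr::select(table, -dplyr::any_of("end_error")),
    no_demographics = dplyr::select(
      table, -dplyr::any_of(c("age", "sex", "occupation"))
    ),
    stop("unknown feature set: ", feature_set)
  )
}

#' Per-trial classification over algorithms and feature sets
#'
#' Runs [cv_classify()] for every trial of a long feature table, for each
#' algorithm and each feature set (`all` features with demographics; the
#' same minus the end-error path-integration feature; the same minus
#' demographics), and flags the best algorithm per trial and metric --
#' the shape of the study's headline results table.
#'
#' @param feature_table Long feature table from [extract_feature_table()]
#'   (or one trial's table; split on `trial_id`).
#' @param feature_sets Subset of
#'   `c("all", "no_end_error", "no_demographics")`.
#' @param algorithms Subset of `c("rf", "svm", "mlp")`.
#' @param seed Master seed.
#' @param importance Keep per-cell importances (as a list-column).
#' @inheritParams cv_classify
#' @return A tibble of class `vrt_summary`: one row per trial x
#'   feature set x algorithm with `mean_f1`, `mean_accuracy`, logical
#'   `best_f1`/`best_accuracy` flags and an `importance` list-column.
#' @export
classify_trials <- function(feature_table,
                            feature_sets = c("all", "no_end_error", "no_demographics"),
                            algorithms = c("rf", "svm", "mlp"),
                            k = 5, seed = 1L, grid = hyper_grid(),
                            nested = TRUE, inner_k = 3,
                            f1_average = "binary", importance = TRUE,
                            n_perm = 5) {
  stopifnot("trial_id" %in% names(feature_table))
  trials <- sort(unique(feature_table$trial_id))
  cells <- tidyr::expand_grid(
    trial_id = trials, feature_set = feature_sets, algorithm = algorithms
  )
  res <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    tab <- feature_table |>
      dplyr::filter(.data$trial_id == cell$trial_id) |>
      feature_set_columns(cell$feature_set)
    cv <- cv_classify(
      tab,
      algorithm = cell$algorithm, k = k,
      seed = derive_seed(
        seed, match(cell$feature_set, feature_sets),
        cell$trial_id * 10 + match(cell$algorithm, algorithms)
      ),
      grid = grid, nested = nested, inner_k = inner_k,
      f1_average = f1_average, importance = importance, n_perm = n_perm
    )
    tibble::tibble(
      trial_id = cell$trial_id, feature_set = cell$feature_set,
      algorithm = cell$algorithm,
      mean_f1 = cv$mean_f1, mean_accuracy = cv$mean_accuracy,
      importance = list(cv$importance)
    )
  })
  res <- res |>
    dplyr::group_by(.data$trial_id, .data$feature_set) |>
    dplyr::mutate(
      best_f1 = .data$mean_f1 == max(.data$mean_f1),
      best_accuracy = .data$mean_accuracy == max(.data$mean_accuracy)
    ) |>
    dplyr::ungroup()
  class(res) <- c("vrt_summary", class(res))
  res
}
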