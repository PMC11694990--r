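#' Classifier specification
#'
#' @param kind One of `"svm_rbf"` (default; RBF-kernel support-vector
#'   machine with balanced class weights and probability scores),
#'   `"random_forest"` or `"gradient_boosted_trees"`.
#' @param grid Data frame of hyperparameter candidates searched by inner
#'   cross-validation; `NULL` for the default grid. For the SVM the defaults
#'   are cost in \{0.1, 1, 10, 100\} and gamma in \{scale heuristic, 0.01,
#'   0.1, 1\} (`NA` encodes the `1 / (p * var(X))` heuristic).
#' @param class_weighting `"balanced"` (weights inverse to class frequency)
#'   or `"none"`.
#' @param seed Integer seed making fits deterministic.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c(
                              "svm_rbf", "random_forest",
                              "gradient_boosted_trees"
                            ),
                            grid = NULL,
                            class_weighting = c("balanced", "none"),
                            seed = 1L) {
  kind <- match.arg(kind)
  class_weighting <- match.arg(class_weighting)
  if (is.null(grid)) {
    grid <- switch(kind,
      svm_rbf = expand.grid(
        cost = c(0.1, 1, 10, 100),
        gamma = c(NA_real_, 0.01, 0.1, 1)
      ),
      random_forest = expand.grid(
        mtry_frac = c(NA_real_, 1 / 3), ntree = 300
      ),
      gradient_boosted_trees = expand.grid(
        nrounds = c(50, 100), max_depth = c(2, 3), eta = 0.3
      )
    )
  }
  if (nrow(grid) == 0L) stop_bad("`grid` must be non-empty.")
  structure(
    list(
      kind = kind, grid = grid, class_weighting = class_weighting,
      seed = as.integer(seed)
    ),
    class = "classifier_spec"
  )
}

as_feature_matrix <- function(table) {
  x <- as.matrix(table[, setdiff(names(table), meta_cols()), drop = FALSE])
  storage.mode(x) <- "double"
  x
}

fit_one <- function(spec, params, x, y, positive) {
  set.seed(spec$seed)
  y <- factor(y, levels = c(setdiff(levels(factor(y)), positive), positive))
  neg <- setdiff(levels(y), positive)
  if (spec$kind == "svm_rbf") {
    gamma <- params$gamma
    if (is.na(gamma)) gamma <- 1 / (ncol(x) * max(var(as.vector(x)), 1e-12))
    cw <- if (spec$class_weighting == "balanced") {
      tab <- table(y)
      stats::setNames(length(y) / (2 * as.numeric(tab)), names(tab))
    } else {
      NULL
    }
    fit <- e1071::svm(
      x = x, y = y, kernel = "radial", cost = params$cost, gamma = gamma,
      class.weights = cw, probability = TRUE, scale = apply(x, 2, sd) > 0
    )
    function(newx) {
      p <- predict(fit, newx, probability = TRUE)
      list(
        label = as.character(p),
        score = attr(p, "probabilities")[, positive]
      )
    }
  } else if (spec$kind == "random_forest") {
    mtry <- if (is.na(params$mtry_frac)) {
      max(1L, floor(sqrt(ncol(x))))
    } else {
      max(1L, floor(ncol(x) * params$mtry_frac))
    }
    cw <- if (spec$class_weighting == "balanced") {
      tab <- table(y)
      stats::setNames(length(y) / (2 * as.numeric(tab)), names(tab))
    } else {
      NULL
    }
    fit <- randomForest::randomForest(
      x = x, y = y, mtry = mtry, ntree = params$ntree, classwt = cw
    )
    function(newx) {
      list(
        label = as.character(predict(fit, newx)),
        score = predict(fit, newx, type = "prob")[, positive]
      )
    }
  } else {
    lab <- as.integer(y == positive)
    w <- if (spec$class_weighting == "balanced") {
      sum(lab == 0) / max(sum(lab == 1), 1L)
    } else {
      1
    }
    fit <- xgboost::xgb.train(
      params = list(
        objective = "binary:logistic", max_depth = params$max_depth,
        eta = params$eta, scale_pos_weight = w, nthread = 1
      ),
      data = xgboost::xgb.DMatrix(x, label = lab, nthread = 1),
      nrounds = params$nrounds, verbose = 0
    )
    function(newx) {
      s <- predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))
      list(label = ifelse(s >= 0.5, positive, neg), score = s)
    }
  }
}

#' Fit a classifier with inner grid search and predict a test set
#'
#' Hyperparameters are selected by stratified inner cross-validation on the
#' training rows only (pooled AUC); the winning configuration is refit on
#' the full training set and applied to the test rows.
#'
#' @param spec A [classifier_spec()].
#' @param train,test Feature tibbles (metadata columns plus numeric
#'   features); `train` must contain both classes.
#' @param positive Positive-class label (default `"acidemic"`).
#' @param inner_splits Folds of the inner search (default 3).
#' @return A tibble with one row per test row: `case_id`, `truth`,
#'   `pred`, `score` (probability of the positive class).
#' @export
fit_predict <- function(spec, train, test, positive = "acidemic",
                        inner_splits = 3L) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (length(unique(train$group)) < 2L) {
    stop_bad("`train` must contain both classes.")
  }
  xtr <- as_feature_matrix(train)
  xte <- as_feature_matrix(test)
  ok <- colSums(is.na(xtr)) == 0L & apply(xtr, 2, sd) > 0
  xtr <- xtr[, ok, drop = FALSE]
  xte <- xte[, ok, drop = FALSE]
  ytr <- train$group

  best <- spec$grid[1L, , drop = FALSE]
  k_inner <- min(inner_splits, min(table(ytr)))
  if (nrow(spec$grid) > 1L && k_inner >= 2L) {
    set.seed(spec$seed)
    inner <- caret::createFolds(factor(ytr), k = k_inner, list = TRUE)
    score_grid <- vapply(seq_len(nrow(spec$grid)), function(g) {
      truth <- character(0)
      sc <- numeric(0)
      for (f in inner) {
        if (length(unique(ytr[-f])) < 2L) next
        pr <- fit_one(
          spec, spec$grid[g, , drop = FALSE],
          xtr[-f, , drop = FALSE], ytr[-f], positive
        )(xtr[f, , drop = FALSE])
        truth <- c(truth, ytr[f])
        sc <- c(sc, pr$score)
      }
      rank_auc(truth == positive, sc)
    }, numeric(1))
    if (!all(is.na(score_grid))) {
      best <- spec$grid[which.max(score_grid), , drop = FALSE]
    }
  }
  pr <- fit_one(spec, best, xtr, ytr, positive)(xte)
  tibble::tibble(
    case_id = test$case_id, truth = test$group,
    pred = pr$label, score = unname(pr$score)
  )
}

# AUC by the rank (Mann-Whitney) formulation, equal to the trapezoidal area
# under the empirical ROC with tie handling; 0.5 for constant scores.
rank_auc <- function(is_pos, score) {
  np <- sum(is_pos)
  nn <- sum(!is_pos)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification performance metrics
#'
#' Computes the six standard metrics from pooled predictions: accuracy,
#' recall (sensitivity), specificity, precision, F1-score and the area
#' under the ROC curve of the continuous scores (trapezoidal, via the rank
#' formulation). Precision is 0 when nothing is predicted positive, and F1
#' is 0 when its denominator vanishes.
#'
#' @param truth,pred Character vectors of true and predicted class labels.
#' @param score Numeric scores for the positive class (for AUC).
#' @param positive Positive-class label (default `"acidemic"`).
#' @return A one-row tibble with `accuracy`, `recall`, `specificity`,
#'   `precision`, `f1`, `auc`.
#' @examples
#' metric_set(
#'   truth = c("a", "a", "b", "b"), pred = c("a", "b", "b", "b"),
#'   score = c(0.9, 0.4, 0.2, 0.1), positive = "a"
#' )
#' @export
metric_set <- function(truth, pred, score = NULL, positive = "acidemic") {
  if (length(truth) == 0L || length(truth) != length(pred)) {
    stop_bad("`truth` and `pred` must be non-empty and the same length.")
  }
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble::tibble(
    accuracy = (tp + tn) / length(truth),
    recall = recall,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    precision = precision,
    f1 = f1,
    auc = if (is.null(score)) NA_real_ else {
      rank_auc(truth == positive, score)
    }
  )
}

#' Run the feature-set tests A-I
#'
#' The evaluation driver: balances the feature table with SMOTE, builds the
#' requested cross-validation folds, and for every feature-set test and
#' classifier fits with inner grid search on each fold's training rows
#' (collinearity-filtered on those rows only) and predicts its test rows.
#' Predictions are pooled across folds and summarised once per
#' (test, classifier) with [metric_set()]; per-fold averaging is available
#' via `aggregate = "averaged"`.
#'
#' @param features Unbalanced feature tibble from [cohort_features()].
#' @param tests Character vector of test ids, subset of `"A"` .. `"I"`.
#' @param classifiers List of [classifier_spec()]s (default: the SVM).
#' @param cv `"custom"` (replica-aware, default) or `"stratified"`.
#' @param plan An [augmentation_plan()]; `NULL` skips balancing.
#' @param collinearity_threshold Absolute-correlation cut applied per fold
#'   (default 0.5).
#' @param n_majority_test Majority rows per custom-CV test set (default 7).
#' @param n_splits Folds for stratified CV (default 20).
#' @param aggregate `"pooled"` (default) or `"averaged"`.
#' @param seed Integer seed fanned out to balancing, folds and fits.
#' @return An object of class `ctg_eval`: a list with `results` (one row
#'   per test x classifier with the six metrics), `predictions` (pooled
#'   per-row predictions) and `settings`.
#' @export
run_feature_set_tests <- function(features, tests = LETTERS[1:9],
                                  classifiers = list(classifier_spec()),
                                  cv = c("custom", "stratified"),
                                  plan = augmentation_plan(),
                                  collinearity_threshold = 0.5,
                                  n_majority_test = 7L,
                                  n_splits = 20L,
                                  aggregate = c("pooled", "averaged"),
                                  seed = 1L) {
  cv <- match.arg(cv)
  aggregate <- match.arg(aggregate)
  stopifnot(all(tests %in% LETTERS[1:9]))

  table <- features
  if (!is.null(plan)) {
    plan$seed <- derive_seed(seed, "smote")
    table <- smote_augment(features, plan)
  }
  folds <- if (cv == "custom") {
    custom_folds(table, n_majority_test, seed = derive_seed(seed, "folds"))
  } else {
    stratified_folds(table, n_splits, seed = derive_seed(seed, "folds"))
  }

  results <- list()
  preds <- list()
  for (spec in classifiers) {
    spec$seed <- derive_seed(seed, paste0("fit_", spec$kind))
    for (test_id in tests) {
      tbl <- select_feature_set(table, test_id)
      fold_preds <- purrr::imap(folds, function(fold, fi) {
        filt <- collinearity_filter(
          tbl, collinearity_threshold, train_rows = fold$train
        )
        p <- fit_predict(spec, filt[fold$train, ], filt[fold$test, ])
        p$fold <- fi
        p$origin <- tbl$origin[fold$test]
        p
      })
      pooled <- dplyr::bind_rows(fold_preds)
      pooled$test <- test_id
      pooled$classifier <- spec$kind
      preds[[paste(spec$kind, test_id)]] <- pooled
      m <- if (aggregate == "pooled") {
        metric_set(pooled$truth, pooled$pred, pooled$score)
      } else {
        per_fold <- dplyr::bind_rows(purrr::map(
          fold_preds, function(p) metric_set(p$truth, p$pred, p$score)
        ))
        dplyr::summarise(
          per_fold, dplyr::across(dplyr::everything(), mean)
        )
      }
      results[[paste(spec$kind, test_id)]] <- dplyr::bind_cols(
        tibble::tibble(classifier = spec$kind, test = test_id), m
      )
    }
  }
  structure(
    list(
      results = dplyr::bind_rows(results),
      predictions = dplyr::bind_rows(preds),
      settings = list(
        cv = cv, aggregate = aggregate, seed = seed,
        n_majority_test = n_majority_test,
        collinearity_threshold = collinearity_threshold
      )
    ),
    class = "ctg_eval"
  )
}

#' @export
print.ctg_eval <- function(x, ...) {
  cat(
    "Feature-set evaluation (", x$settings$cv, " CV, ",
    x$settings$aggregate, " metrics)\n\n",
    sep = ""
  )
  print(x$results, n = Inf)
  invisible(x)
}

#' Tidy a feature-set evaluation
#'
#' @param x A `ctg_eval` from [run_feature_set_tests()].
#' @param ... Unused.
#' @return A long tibble: `classifier`, `test`, `metric`, `value`.
#' @export
tidy.ctg_eval <- function(x, ...) {
  tidyr::pivot_longer(
    x$results,
    cols = -c("classifier", "test"),
    names_to = "metric", values_to = "value"
  )
}

#' One-line summary of a feature-set evaluation
#'
#' @param x A `ctg_eval`.
#' @param ... Unused.
#' @return A one-row tibble with the best test by F1 for each classifier's
#'   best row plus the settings used.
#' @export
glance.ctg_eval <- function(x, ...) {
  best <- x$results[which.max(x$results$f1), ]
  tibble::tibble(
    n_tests = length(unique(x$results$test)),
    n_classifiers = length(unique(x$results$classifier)),
    best_classifier = best$classifier,
    best_test = best$test,
    best_f1 = best$f1,
    best_auc = best$auc,
    cv = x$settings$cv
  )
}

#' ROC points for an evaluation
#'
#' @param eval A `ctg_eval`.
#' @param test,classifier Which pooled prediction set to trace (defaults:
#'   first of each present).
#' @return A tibble of ROC points (`threshold`, `fpr`, `tpr`) computed with
#'   \pkg{pROC}.
#' @export
roc_points <- function(eval, test = NULL, classifier = NULL) {
  stopifnot(inherits(eval, "ctg_eval"))
  p <- eval$predictions
  test <- test %||% p$test[1]
  classifier <- classifier %||% p$classifier[1]
  p <- p[p$test == test & p$classifier == classifier, ]
  r <- pROC::roc(
    response = p$truth == "acidemic", predictor = p$score,
    quiet = TRUE, direction = "<"
  )
  tibble::tibble(
    test = test, classifier = classifier,
    threshold = r$thresholds, fpr = 1 - r$specificities,
    tpr = r$sensitivities
  )
}

#' Plot ROC curves for an evaluation
#'
#' @param object A `ctg_eval`.
#' @param tests Feature-set tests to draw (default: all present).
#' @param classifier Classifier to draw (default: first present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctg_eval <- function(object, tests = NULL,
                              classifier = NULL, ...) {
  tests <- tests %||% unique(object$predictions$test)
  classifier <- classifier %||% object$predictions$classifier[1]
  pts <- dplyr::bind_rows(
    purrr::map(tests, function(tt) roc_points(object, tt, classifier))
  )
  ggplot2::ggplot(
    pts, ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$test)
  ) +
    ggplot2::geom_abline(
      slope = 1, intercept = 0, linetype = "dashed", colour = "red"
    ) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      colour = "Feature set",
      title = paste("ROC,", classifier, "classifier")
    ) +
    ggplot2::theme_minimal()
}
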