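separable_toy <- function(n = 40, seed = 1L) {
  set.seed(seed)
  half <- n / 2
  x1 <- c(rnorm(half, -3, 0.4), rnorm(half, 3, 0.4))
  x2 <- c(rnorm(half, -3, 0.4), rnorm(half, 3, 0.4))
  tibble::tibble(
    case_id = sprintf("t%02d", 1:n),
    group = rep(c("nonacidemic", "acidemic"), each = half),
    ph = rep(c(7.3, 7.1), each = half),
    origin = "original",
    `maternal-fetal NRC — h2-a — trend` = x1,
    `maternal-fetal NCD — h2-a — trend` = x2
  )
}

test_that("metric arithmetic matches hand-computed confusion tables", {
  # TP=2, FP=1, TN=3, FN=0
  truth <- c("a", "a", "n", "n", "n", "n")
  pred <- c("a", "a", "a", "n", "n", "n")
  m <- metric_set(truth, pred, positive = "a")
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$specificity, 3 / 4)

  perfect <- metric_set(truth, truth, score = as.numeric(truth == "a"),
    positive = "a"
  )
  expect_true(all(unlist(perfect) == 1))

  expect_equal(
    metric_set(truth, pred, score = rep(0.5, 6), positive = "a")$auc, 0.5
  )
})

test_that("metrics agree with brute-force enumeration on fuzzed labels", {
  set.seed(31)
  for (r in 1:1000) {
    n <- sample(2:30, 1)
    truth <- sample(c("acidemic", "nonacidemic"), n, replace = TRUE)
    pred <- sample(c("acidemic", "nonacidemic"), n, replace = TRUE)
    m <- metric_set(truth, pred)
    o <- oracle_metrics(truth, pred, "acidemic")
    expect_equal(
      unlist(m[, names(o)]), o,
      ignore_attr = TRUE, tolerance = 1e-12
    )
  }
})

test_that("rank AUC agrees with pROC's trapezoidal area", {
  set.seed(8)
  for (r in 1:25) {
    n <- sample(10:60, 1)
    truth <- sample(c("acidemic", "nonacidemic"), n, replace = TRUE,
      prob = c(0.4, 0.6)
    )
    if (length(unique(truth)) < 2) next
    score <- round(runif(n), 2) # ties included
    m <- metric_set(truth, truth, score)
    ref <- as.numeric(pROC::auc(
      response = truth == "acidemic", predictor = score,
      quiet = TRUE, direction = "<"
    ))
    expect_equal(m$auc, ref, tolerance = 1e-12)
  }
})

test_that("a separable toy is classified perfectly by every backend", {
  toy <- separable_toy(40, seed = 2)
  test <- separable_toy(20, seed = 3)
  for (kind in c("svm_rbf", "random_forest", "gradient_boosted_trees")) {
    p <- fit_predict(classifier_spec(kind, seed = 4), toy, test)
    expect_equal(p$pred, test$group, info = kind)
    expect_gt(metric_set(p$truth, p$pred, p$score)$auc, 0.99)
  }
})

test_that("fits are deterministic under seed and reject one-class training", {
  toy <- separable_toy(30, seed = 5)
  test <- separable_toy(10, seed = 6)
  spec <- classifier_spec(seed = 9)
  expect_identical(
    fit_predict(spec, toy, test),
    fit_predict(spec, toy, test)
  )
  one <- toy[toy$group == "acidemic", ]
  expect_error(fit_predict(spec, one, test), "both classes")
})

test_that("label permutation destroys test performance", {
  aucs <- vapply(1:10, function(s) {
    toy <- separable_toy(60, seed = 100 + s)
    set.seed(s)
    toy$group <- sample(toy$group)
    test <- toy[41:60, ]
    train <- toy[1:40, ]
    if (length(unique(train$group)) < 2 ||
      length(unique(test$group)) < 2) {
      return(0.5)
    }
    p <- fit_predict(
      classifier_spec(grid = data.frame(cost = 1, gamma = 0.1), seed = s),
      train, test
    )
    metric_set(p$truth, p$pred, p$score)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("the evaluation driver produces a full report with pooling", {
  tbl <- toy_feature_table(7, 54, p = 6, seed = 12)
  ev <- run_feature_set_tests(
    tbl,
    tests = c("A", "B"),
    classifiers = list(
      classifier_spec(grid = data.frame(cost = 1, gamma = 0.1))
    ),
    seed = 3
  )
  expect_s3_class(ev, "ctg_eval")
  expect_equal(nrow(ev$results), 2)
  expect_named(
    ev$results,
    c(
      "classifier", "test", "accuracy", "recall", "specificity",
      "precision", "f1", "auc"
    )
  )
  # pooled predictions: 7 folds x 14 test rows per test id
  expect_equal(sum(ev$predictions$test == "A"), 98)

  td <- tidy(ev)
  expect_equal(nrow(td), 2 * 6)
  gl <- glance(ev)
  expect_equal(gl$n_tests, 2)
  expect_true(gl$best_test %in% c("A", "B"))

  rp <- roc_points(ev, test = "A")
  expect_true(all(diff(rp$tpr) >= 0 | diff(rp$fpr) >= 0))
  plt <- autoplot(ev, tests = "A")
  expect_s3_class(plt, "ggplot")
})

test_that("pooled and averaged aggregation differ in general", {
  tbl <- toy_feature_table(7, 54, p = 6, seed = 14)
  spec <- list(classifier_spec(grid = data.frame(cost = 1, gamma = 0.1)))
  pooled <- run_feature_set_tests(tbl,
    tests = "A", classifiers = spec,
    aggregate = "pooled", seed = 5
  )
  averaged <- run_feature_set_tests(tbl,
    tests = "A", classifiers = spec,
    aggregate = "averaged", seed = 5
  )
  expect_false(isTRUE(all.equal(pooled$results$auc, averaged$results$auc)))
})
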