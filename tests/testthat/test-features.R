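test_that("feature grid has 9 families x segments x 2 components", {
  rec <- generate_cohort(cohort_config(
    n_nonacidemic = 1, n_acidemic = 0, duration_min = 120, jitter_min = 0,
    seed = 13
  ))
  row <- subject_features(rec[1, ])
  feat_cols <- setdiff(names(row), c("case_id", "group", "ph", "origin"))
  expect_length(feat_cols, 12 * 2 * 9) # 216 before the 30-min drop

  info <- parse_feature_columns(feat_cols)
  expect_setequal(unique(info$component), c("trend", "residual"))
  expect_equal(length(unique(info$family)), 9)
  expect_false(any(duplicated(feat_cols)))

  # over-time families undefined at their own reference window
  ref <- info$column[info$label == "h1-a" & info$scope != "maternal-fetal" &
    info$metric != "CR"]
  expect_true(all(is.na(row[, ref])))
  other <- setdiff(feat_cols, ref)
  expect_false(anyNA(row[, other]))
})

test_that("dropping the first 30 minutes leaves the h1-d..h2-f grid", {
  rec <- generate_cohort(cohort_config(
    n_nonacidemic = 1, n_acidemic = 0, duration_min = 120, jitter_min = 0,
    seed = 13
  ))
  tbl <- cohort_features(rec, drop_first_min = 30)
  feat_cols <- setdiff(names(tbl), c("case_id", "group", "ph", "origin"))
  expect_length(feat_cols, 9 * 2 * 9) # 162
  info <- parse_feature_columns(feat_cols)
  expect_setequal(
    unique(info$label),
    c("h1-d", "h1-e", "h1-f", paste0("h2-", letters[1:6]))
  )
  expect_false(anyNA(as.matrix(tbl[, feat_cols])))
})

test_that("collinearity filter keeps one column per correlated group", {
  set.seed(7)
  base <- rnorm(100)
  tbl <- toy_feature_table(7, 93, p = 2, seed = 7)
  tbl$`fetal NRC — h2-a — trend` <- base
  tbl$`fetal NRC — h2-b — trend` <- base # duplicate
  tbl$`fetal NRC — h2-c — trend` <- base + rnorm(100, 0, 0.01)
  out <- collinearity_filter(tbl, 0.5)
  kept <- setdiff(names(out), c("case_id", "group", "ph", "origin"))
  chain <- paste0("fetal NRC — h2-", c("a", "b", "c"), " — trend")
  expect_length(intersect(kept, chain), 1)
  # canonical order keeps the earliest slot
  expect_true(chain[1] %in% kept)
  m <- abs(cor(as.matrix(out[, kept])))
  diag(m) <- 0
  expect_lt(max(m), 0.5 + 1e-12)
})

test_that("orthogonal noise columns all survive the filter", {
  set.seed(11)
  tbl <- toy_feature_table(7, 93, p = 10, seed = 11)
  out <- collinearity_filter(tbl, 0.5)
  expect_length(setdiff(names(out), c("case_id", "group", "ph", "origin")), 10)
})

test_that("constant columns are dropped before correlation", {
  tbl <- toy_feature_table(7, 20, p = 3, seed = 2)
  tbl$`fetal NRC — h2-a — trend` <- 1
  out <- collinearity_filter(tbl, 0.5)
  expect_false("fetal NRC — h2-a — trend" %in% names(out))
})

test_that("feature-set tests A-I select the documented families", {
  rec <- generate_cohort(cohort_config(
    n_nonacidemic = 1, n_acidemic = 0, duration_min = 120, jitter_min = 0,
    seed = 13
  ))
  tbl <- cohort_features(rec)
  feat_info <- function(t) {
    parse_feature_columns(
      setdiff(names(t), c("case_id", "group", "ph", "origin"))
    )
  }
  e <- feat_info(select_feature_set(tbl, "E"))
  expect_setequal(unique(e$scope), "maternal-fetal")
  expect_setequal(unique(e$component), "trend")
  expect_setequal(unique(e$metric), c("CR", "NRC", "NCD"))

  g <- feat_info(select_feature_set(tbl, "G"))
  expect_setequal(unique(g$metric), c("NRC", "NCD"))
  expect_equal(
    sort(setdiff(e$column[e$metric != "CR"], g$column)), character(0)
  )

  i <- feat_info(select_feature_set(tbl, "I"))
  f <- feat_info(select_feature_set(tbl, "F"))
  expect_equal(nrow(i), nrow(e) + nrow(f))
  expect_setequal(unique(i$component), c("trend", "residual"))

  a <- feat_info(select_feature_set(tbl, "A"))
  expect_setequal(unique(a$scope), c("fetal", "maternal", "maternal-fetal"))
  expect_setequal(unique(a$component), "trend")
  cd <- feat_info(select_feature_set(tbl, "D"))
  expect_setequal(unique(cd$scope), c("fetal", "maternal"))
  expect_setequal(unique(cd$component), "residual")

  expect_error(select_feature_set(tbl, "Z"), "test_id")
})

test_that("feature extraction is deterministic", {
  rec <- small_cohort(seed = 19, n_non = 1, n_acid = 0, duration_min = 45)
  expect_identical(subject_features(rec[1, ]), subject_features(rec[1, ]))
})

test_that("null cohorts show no systematic per-column group differences", {
  # effect_size = 0: a two-sample test at alpha = 0.01 should reject in
  # roughly 1% of feature columns, and never in more than 5% on average
  rejects <- c()
  for (s in 1:4) {
    cohort <- generate_cohort(cohort_config(
      n_nonacidemic = 8, n_acidemic = 8, duration_min = 45, jitter_min = 0,
      effect_size = 0, seed = 400 + s
    ))
    tbl <- cohort_features(cohort, drop_first_min = 0)
    feats <- setdiff(names(tbl), c("case_id", "group", "ph", "origin"))
    p <- vapply(feats, function(f) {
      x <- tbl[[f]]
      if (anyNA(x) || sd(x) == 0) return(NA_real_)
      suppressWarnings(
        stats::wilcox.test(x ~ tbl$group, exact = FALSE)$p.value
      )
    }, numeric(1))
    rejects <- c(rejects, mean(p < 0.01, na.rm = TRUE))
  }
  expect_lte(mean(rejects), 0.05)
})
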