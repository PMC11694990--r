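#' Replica-aware custom cross-validation folds
#'
#' One fold per original minority case: the test set holds that original,
#' all synthetic replicas derived from it, and `n_majority_test` majority
#' rows; everything else trains. The model therefore never sees the held-out
#' original nor any of its replicas during training, removing the
#' augmentation leakage that inflates conventional k-fold results on
#' SMOTE-balanced data. Majority test rows are sampled without replacement
#' and disjointly across folds whenever the majority class is large enough.
#'
#' @param table Feature tibble with `group` and `origin` columns (after
#'   [smote_augment()]).
#' @param n_majority_test Majority rows per test set (default 7).
#' @param seed Integer seed for the majority sampling.
#' @param minority_group Minority class label (default `"acidemic"`).
#' @return A list of folds, each a list with integer row indices `train`
#'   and `test`.
#' @export
custom_folds <- function(table, n_majority_test = 7L, seed = 1L,
                         minority_group = "acidemic") {
  if (!all(c("group", "origin") %in% names(table))) {
    stop_bad("`table` must carry `group` and `origin` provenance columns.")
  }
  seed_ids <- provenance_seed_id(table$origin, table$case_id)
  originals <- table$case_id[
    table$group == minority_group & table$origin == "original"
  ]
  if (length(originals) == 0L) stop_bad("no original minority rows found.")
  majority <- which(table$group != minority_group)
  n_need <- length(originals) * n_majority_test

  set.seed(seed)
  if (n_need <= length(majority)) {
    picks <- matrix(sample(majority, n_need), ncol = length(originals))
  } else {
    picks <- vapply(
      seq_along(originals),
      function(i) sample(majority, n_majority_test),
      integer(n_majority_test)
    )
  }
  lapply(seq_along(originals), function(i) {
    min_test <- which(seed_ids == originals[i] &
      table$group == minority_group)
    test <- sort(c(min_test, picks[, i]))
    list(train = setdiff(seq_len(nrow(table)), test), test = test)
  })
}

#' Stratified k-fold cross-validation folds
#'
#' Standard stratified folds: every row is tested exactly once and each test
#' fold preserves the class proportions up to rounding.
#'
#' @param table Feature tibble with a `group` column.
#' @param n_splits Number of folds (default 20). Must be at least 2 and no
#'   larger than the minority class count.
#' @param seed Integer seed.
#' @return A list of folds as in [custom_folds()].
#' @export
stratified_folds <- function(table, n_splits = 20L, seed = 1L) {
  y <- factor(table$group)
  if (nlevels(y) < 2L) stop_bad("both classes must be present.")
  if (n_splits < 2L) stop_bad("`n_splits` must be at least 2.")
  if (n_splits > min(table(y))) {
    stop_bad("`n_splits` exceeds the minority class count.")
  }
  set.seed(seed)
  test_sets <- caret::createFolds(y, k = n_splits, list = TRUE)
  lapply(test_sets, function(test) {
    list(train = setdiff(seq_len(nrow(table)), test), test = sort(test))
  })
}
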