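#' SMOTE augmentation plan
#'
#' @param n_synthetic_per_original Synthetic minority cases generated from
#'   each original one (default 6, growing 7 originals to 49 cases).
#' @param k_neighbors Number of nearest minority neighbors a partner is drawn
#'   from (default 5).
#' @param seed Integer seed.
#' @return A list of class `augmentation_plan`.
#' @export
augmentation_plan <- function(n_synthetic_per_original = 6L,
                              k_neighbors = 5L, seed = 1L) {
  assert_scalar_number(n_synthetic_per_original, "n_synthetic_per_original",
    lower = 0
  )
  assert_scalar_number(k_neighbors, "k_neighbors", lower = 1)
  structure(
    list(
      n_synthetic_per_original = as.integer(n_synthetic_per_original),
      k_neighbors = as.integer(k_neighbors),
      seed = as.integer(seed)
    ),
    class = "augmentation_plan"
  )
}

#' Oversample the minority class with SMOTE
#'
#' For each original minority (acidemic) row, generates
#' `n_synthetic_per_original` synthetic rows by the classic two-step
#' construction: take the difference between the row's feature vector and
#' one of its `k_neighbors` nearest minority neighbors (Euclidean distance),
#' multiply it by a random number in \[0, 1\], and add it to the row. Every
#' synthetic case therefore lies on the segment between its seed case and a
#' minority neighbor, and records its seed's identity in `origin` as
#' `synthetic_replica:<seed_id>` so replica-aware validation can group them.
#' Original rows are never altered.
#'
#' @param table Feature tibble with `case_id`, `group`, `origin` metadata.
#' @param plan An [augmentation_plan()].
#' @param minority_group Label of the minority class (default `"acidemic"`).
#' @return The table with the synthetic rows appended.
#' @export
smote_augment <- function(table, plan = augmentation_plan(),
                          minority_group = "acidemic") {
  stopifnot(inherits(plan, "augmentation_plan"))
  min_rows <- which(table$group == minority_group &
    table$origin == "original")
  if (length(min_rows) < 2L) {
    stop_bad("SMOTE needs at least 2 original minority rows.")
  }
  k <- min(plan$k_neighbors, length(min_rows) - 1L)
  feats <- setdiff(names(table), meta_cols())
  x <- as.matrix(table[min_rows, feats, drop = FALSE])
  complete <- colSums(is.na(x)) == 0L
  d <- as.matrix(stats::dist(x[, complete, drop = FALSE]))

  set.seed(plan$seed)
  synth <- list()
  for (i in seq_along(min_rows)) {
    nbr_order <- order(d[i, ])
    nbrs <- setdiff(nbr_order, i)[seq_len(k)]
    for (r in seq_len(plan$n_synthetic_per_original)) {
      q <- nbrs[sample.int(k, 1L)]
      lambda <- runif(1)
      new_row <- table[min_rows[i], ]
      new_row[, feats] <- as.list(x[i, ] + lambda * (x[q, ] - x[i, ]))
      new_row$case_id <- sprintf(
        "%s_synth%02d", table$case_id[min_rows[i]], r
      )
      new_row$origin <- paste0(
        "synthetic_replica:", table$case_id[min_rows[i]]
      )
      synth[[length(synth) + 1L]] <- new_row
    }
  }
  dplyr::bind_rows(table, synth)
}

#' Seed case of each row's provenance
#'
#' @param origin Character vector of `origin` values (`"original"` or
#'   `"synthetic_replica:<id>"`).
#' @param case_id Matching case identifiers.
#' @return For each row, the id of the original case it descends from
#'   (itself for originals).
#' @export
provenance_seed_id <- function(origin, case_id) {
  ifelse(
    origin == "original", case_id,
    sub("^synthetic_replica:", "", origin)
  )
}
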