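feature_families <- function() {
  c(
    "fetal compression ratio", "maternal compression ratio",
    "maternal-fetal compression ratio",
    "fetal NRC", "maternal NRC", "maternal-fetal NRC",
    "fetal NCD", "maternal NCD", "maternal-fetal NCD"
  )
}

feature_name <- function(family, label, component) {
  paste(family, label, component, sep = " — ")
}

#' Parse feature-table column names
#'
#' Splits column names of the form
#' `"<family> — <hour>-<slot> — <component>"` into their parts.
#'
#' @param columns Character vector of feature column names.
#' @return A tibble with `column`, `family`, `label`, `hour`, `slot`,
#'   `component` and `scope` (`fetal`, `maternal` or `maternal-fetal`).
#' @export
parse_feature_columns <- function(columns) {
  parts <- stringr::str_split_fixed(columns, " — ", 3)
  family <- parts[, 1]
  scope <- dplyr::case_when(
    stringr::str_starts(family, "maternal-fetal") ~ "maternal-fetal",
    stringr::str_starts(family, "maternal") ~ "maternal",
    TRUE ~ "fetal"
  )
  tibble::tibble(
    column = columns,
    family = family,
    label = parts[, 2],
    hour = substr(parts[, 2], 1, 2),
    slot = substr(parts[, 2], 4, 4),
    component = parts[, 3],
    scope = scope,
    metric = dplyr::case_when(
      stringr::str_ends(family, "compression ratio") ~ "CR",
      stringr::str_ends(family, "NRC") ~ "NRC",
      TRUE ~ "NCD"
    )
  )
}

# Serialization offset per component: residuals are zero-centered, so they
# are shifted into the middle of the byte range before DEFLATE-based
# measures.
component_offset <- function(component) {
  if (component == "residual") 128 else 0
}

#' Compression-index features for one subject
#'
#' Runs the per-subject chain (preprocess, per channel/component Lloyd-Max
#' quantization on the full series, segment-level compression measures) and
#' returns one feature row. Per kept 10-minute window and per component
#' (trend, residual), nine index families are computed:
#'
#' * fetal / maternal / maternal-fetal compression ratio: DEFLATE ratio of
#'   the serialized window (for the bivariate family, of the fetal window
#'   concatenated with the simultaneous maternal window);
#' * maternal-fetal NRC: code length of the fetal window under a
#'   finite-context model of the simultaneous maternal window (x = fetal,
#'   y = maternal — the direction measuring fetal dependence on the mother);
#' * fetal / maternal NRC over time: each window coded against the subject's
#'   first kept window of the same channel and component;
#' * maternal-fetal NCD, and fetal / maternal NCD over time, analogously.
#'
#' Over-time families are undefined (`NA`) at the reference window itself.
#'
#' @param record One-row cohort tibble.
#' @param trend_cfg A [trend_config()].
#' @param fcm_cfg An [fcm_config()] (defaults: alphabet 20, k = 6, d = 6).
#' @param quant_L Lloyd-Max alphabet size (default `fcm_cfg$alphabet_size`).
#' @return A one-row tibble: `case_id`, `group`, `ph`, `origin`, plus one
#'   numeric column per (family, window, component).
#' @export
subject_features <- function(record, trend_cfg = trend_config(),
                             fcm_cfg = fcm_config(),
                             quant_L = fcm_cfg$alphabet_size) {
  prep <- preprocess_subject(record, trend_cfg)
  segs <- prep$segments

  # one quantizer per (channel, component), fitted on the full series
  codes_for <- function(channel, component) {
    full <- prep$series$samples[[
      which(prep$series$channel == channel &
        prep$series$component == component)
    ]]
    q <- fit_lloyd_max(full, L = quant_L)
    function(x) quantize(x, q)
  }

  vals <- list(
    case_id = record$subject_id[1], group = record$group[1],
    ph = record$ph[1], origin = record$origin[1]
  )
  for (component in c("trend", "residual")) {
    off <- component_offset(component)
    fseg <- segs[segs$channel == "fetal" & segs$component == component, ]
    mseg <- segs[segs$channel == "maternal" & segs$component == component, ]
    labels <- fseg$label
    qf <- codes_for("fetal", component)
    qm <- codes_for("maternal", component)

    ref_label <- labels[1] # first kept window = over-time reference
    f_ref <- fseg$samples[[1]]
    m_ref <- mseg$samples[[1]]
    fcm_f_ref <- fit_fcm(qf(f_ref), fcm_cfg)
    fcm_m_ref <- fit_fcm(qm(m_ref), fcm_cfg)
    denom <- function(x) length(x) * log2(fcm_cfg$alphabet_size)

    for (i in seq_along(labels)) {
      lab <- labels[i]
      f <- fseg$samples[[i]]
      m <- mseg$samples[[i]]
      is_ref <- lab == ref_label
      cf <- qf(f)
      cm <- qm(m)

      v <- c(
        compression_ratio(f, off),
        compression_ratio(m, off),
        compression_ratio(c(f, m), off),
        if (is_ref) NA_real_ else {
          relative_code_length(cf, fcm_f_ref)$bits / denom(cf)
        },
        if (is_ref) NA_real_ else {
          relative_code_length(cm, fcm_m_ref)$bits / denom(cm)
        },
        nrc(cf, cm, fcm_cfg),
        if (is_ref) NA_real_ else ncd(f, f_ref, off),
        if (is_ref) NA_real_ else ncd(m, m_ref, off),
        ncd(f, m, off)
      )
      names(v) <- feature_name(feature_families(), lab, component)
      vals <- c(vals, as.list(v))
    }
  }
  tibble::as_tibble(vals)
}

#' Feature table for a whole cohort
#'
#' Maps [subject_features()] over every subject and optionally removes the
#' columns from the first `drop_first_min` minutes of the recording
#' (windows `h1-a`, `h1-b`, `h1-c` for the default 30), which not all
#' subjects complete.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param trend_cfg,fcm_cfg,quant_L Passed to [subject_features()].
#' @param drop_first_min Minutes removed from the start of the feature grid
#'   (default 30; use 0 to keep everything).
#' @return A feature tibble, one row per subject.
#' @export
cohort_features <- function(cohort, trend_cfg = trend_config(),
                            fcm_cfg = fcm_config(),
                            quant_L = fcm_cfg$alphabet_size,
                            drop_first_min = 30) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    subject_features(cohort[i, ], trend_cfg, fcm_cfg, quant_L)
  })
  tbl <- dplyr::bind_rows(rows)
  if (drop_first_min > 0) tbl <- drop_early_segments(tbl, drop_first_min)
  tbl
}

#' Drop features from the first minutes of the recording
#'
#' @param table Feature tibble.
#' @param minutes Segments whose nominal window lies entirely within the
#'   first `minutes` minutes are removed (default 30: windows `h1-a..c`).
#' @return The reduced tibble.
#' @export
drop_early_segments <- function(table, minutes = 30) {
  n_slots <- floor(minutes / 10)
  drop_labels <- slot_labels()[seq_len(n_slots)]
  info <- parse_feature_columns(setdiff(
    names(table), c("case_id", "group", "ph", "origin")
  ))
  drop_cols <- info$column[info$label %in% drop_labels]
  dplyr::select(table, -dplyr::all_of(drop_cols))
}

meta_cols <- function() c("case_id", "group", "ph", "origin")

#' Reduce collinear features
#'
#' Walks the feature columns in canonical order (family, component, hour,
#' slot) and keeps a column only if its absolute Pearson correlation with
#' every already-kept column is at or below `threshold`; within each group
#' of mutually correlated columns the earliest survives. Constant columns
#' (undefined correlation) are dropped first. Correlations are computed on
#' `train_rows` only, so the retained set can be frozen on training data and
#' applied to held-out rows without leakage.
#'
#' @param table Feature tibble.
#' @param threshold Absolute-correlation cut (default 0.5).
#' @param train_rows Integer row indices used to estimate correlations
#'   (default: all rows).
#' @return The tibble restricted to the retained columns (metadata columns
#'   are always kept). Dropped column names are stored in attribute
#'   `dropped`.
#' @export
collinearity_filter <- function(table, threshold = 0.5, train_rows = NULL) {
  if (nrow(table) < 2L) stop_bad("`table` must have at least 2 rows.")
  train_rows <- train_rows %||% seq_len(nrow(table))
  feats <- setdiff(names(table), meta_cols())
  info <- parse_feature_columns(feats)
  ord <- order(
    match(info$family, feature_families()),
    match(info$component, c("trend", "residual")),
    info$hour, info$slot
  )
  feats <- feats[ord]

  x <- as.matrix(table[train_rows, feats, drop = FALSE])
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  feats <- feats[!is.na(sds) & sds > 0]
  x <- x[, feats, drop = FALSE]

  kept <- character(0)
  for (f in feats) {
    if (length(kept) == 0L) {
      kept <- f
      next
    }
    r <- suppressWarnings(
      abs(stats::cor(x[, f], x[, kept, drop = FALSE],
        use = "pairwise.complete.obs"
      ))
    )
    if (all(is.na(r)) || max(r, na.rm = TRUE) <= threshold) kept <- c(kept, f)
  }
  out <- dplyr::select(
    table, dplyr::all_of(meta_cols()), dplyr::all_of(kept)
  )
  attr(out, "dropped") <- setdiff(
    setdiff(names(table), meta_cols()), kept
  )
  out
}

#' Select the columns for one of the feature-set tests A-I
#'
#' The nine tests probe which index families and which signal component
#' carry the discriminative information:
#' * A / B: all nine families, trend / residual;
#' * C / D: maternal and fetal (univariate) families, trend / residual;
#' * E / F: maternal-fetal (bivariate) families, trend / residual;
#' * G / H: maternal-fetal NRC and NCD only (no compression ratio),
#'   trend / residual;
#' * I: maternal-fetal families, trend and residual together.
#'
#' @param table Feature tibble.
#' @param test_id One of `"A"` .. `"I"`.
#' @return The tibble restricted to the test's columns (plus metadata).
#' @export
select_feature_set <- function(table, test_id) {
  if (!test_id %in% LETTERS[1:9]) {
    stop_bad("`test_id` must be one of A..I.")
  }
  info <- parse_feature_columns(setdiff(names(table), meta_cols()))
  comp <- switch(test_id,
    A = "trend", B = "residual", C = "trend", D = "residual",
    E = "trend", F = "residual", G = "trend", H = "residual",
    I = c("trend", "residual")
  )
  scope <- switch(test_id,
    A = , B = c("fetal", "maternal", "maternal-fetal"),
    C = , D = c("fetal", "maternal"),
    E = , F = , I = "maternal-fetal",
    G = , H = "maternal-fetal"
  )
  metric <- switch(test_id,
    G = , H = c("NRC", "NCD"),
    c("CR", "NRC", "NCD")
  )
  keep <- info$column[
    info$component %in% comp & info$scope %in% scope & info$metric %in% metric
  ]
  dplyr::select(table, dplyr::all_of(meta_cols()), dplyr::all_of(keep))
}

#' Write a feature table with a JSON sidecar
#'
#' @param table Feature tibble.
#' @param path CSV output path; a `<path>.json` sidecar records the columns
#'   and any configuration passed via `meta`.
#' @param meta Named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, meta = list()) {
  readr::write_csv(table, path)
  jsonlite::write_json(
    c(list(columns = setdiff(names(table), meta_cols())), meta),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
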