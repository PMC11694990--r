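#' Assemble a full run configuration
#'
#' Bundles the per-stage configurations with a single global seed that is
#' fanned out deterministically to every random stage (cohort generation,
#' SMOTE, folds, classifier fits).
#'
#' @param cohort A [cohort_config()].
#' @param trend A [trend_config()].
#' @param fcm An [fcm_config()].
#' @param plan An [augmentation_plan()].
#' @param classifiers List of [classifier_spec()]s.
#' @param tests Feature-set test ids to run.
#' @param cv `"custom"` or `"stratified"`.
#' @param drop_first_min Minutes of features dropped from the recording
#'   start (default 30).
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       trend = trend_config(),
                       fcm = fcm_config(),
                       plan = augmentation_plan(),
                       classifiers = list(classifier_spec()),
                       tests = LETTERS[1:9],
                       cv = "custom",
                       drop_first_min = 30,
                       seed = 1L) {
  stopifnot(
    inherits(cohort, "cohort_config"), inherits(trend, "trend_config"),
    inherits(fcm, "fcm_config"), inherits(plan, "augmentation_plan")
  )
  structure(
    list(
      cohort = cohort, trend = trend, fcm = fcm, plan = plan,
      classifiers = classifiers, tests = tests, cv = cv,
      drop_first_min = drop_first_min, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys (`cohort`, `trend`, `fcm`, `plan`, `tests`, `cv`,
#' `classifiers`, `drop_first_min`, `seed`) map onto the corresponding
#' constructor arguments; omitted keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  classifiers <- if (is.null(y$classifiers)) {
    list(classifier_spec())
  } else {
    lapply(y$classifiers, function(k) classifier_spec(kind = k))
  }
  run_config(
    cohort = build(cohort_config, y$cohort),
    trend = build(trend_config, y$trend),
    fcm = build(fcm_config, y$fcm),
    plan = build(augmentation_plan, y$plan),
    classifiers = classifiers,
    tests = y$tests %||% LETTERS[1:9],
    cv = y$cv %||% "custom",
    drop_first_min = y$drop_first_min %||% 30,
    seed = y$seed %||% 1L
  )
}

#' Run the whole analysis pipeline
#'
#' Executes simulate, preprocess + feature extraction, balancing,
#' cross-validated classification and reporting in order, writing every
#' artifact into `out_dir` together with a manifest (file list with MD5
#' checksums, the seed, and a hash of the configuration). Re-running with an
#' identical configuration reproduces identical outputs. A stage failure is
#' recorded in the manifest and re-raised.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; created if missing. `NULL` skips all
#'   file output.
#' @return Invisibly, a list with `cohort`, `features`, `eval` (a
#'   `ctg_eval`) and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  cfg_hash <- config_hash(config)
  manifest <- list(
    config_hash = cfg_hash, seed = config$seed, status = "running",
    files = list()
  )
  finish <- function(status, error = NULL) {
    manifest$status <<- status
    if (!is.null(error)) manifest$error <<- conditionMessage(error)
    if (!is.null(out_dir)) {
      writeLines(log_lines, file.path(out_dir, "run.log"))
      files <- setdiff(list.files(out_dir), "manifest.json")
      manifest$files <<- lapply(files, function(f) {
        list(
          file = f,
          md5 = unname(tools::md5sum(file.path(out_dir, f)))
        )
      })
      jsonlite::write_json(
        manifest, file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    }
  }

  result <- tryCatch(
    {
      cohort_cfg <- config$cohort
      cohort_cfg$seed <- derive_seed(config$seed, "cohort")
      note("simulate: ", cohort_cfg$n_nonacidemic + cohort_cfg$n_acidemic,
        " subjects"
      )
      cohort <- generate_cohort(cohort_cfg)

      note("features: extracting compression indices")
      features <- cohort_features(
        cohort, config$trend, config$fcm,
        drop_first_min = config$drop_first_min
      )
      if (!is.null(out_dir)) {
        write_feature_table(
          features, file.path(out_dir, "features.csv"),
          meta = list(config_hash = cfg_hash, seed = config$seed)
        )
      }

      note("evaluate: tests ", paste(config$tests, collapse = ","))
      eval <- run_feature_set_tests(
        features,
        tests = config$tests, classifiers = config$classifiers,
        cv = config$cv, plan = config$plan, seed = config$seed
      )
      if (!is.null(out_dir)) {
        readr::write_csv(eval$results, file.path(out_dir, "metrics.csv"))
        jsonlite::write_json(
          eval$results, file.path(out_dir, "metrics.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE
        )
        readr::write_csv(
          eval$predictions, file.path(out_dir, "predictions.csv")
        )
        readr::write_csv(
          dplyr::bind_rows(purrr::map(
            unique(eval$predictions$test),
            function(tt) roc_points(eval, tt)
          )),
          file.path(out_dir, "roc_points.csv")
        )
      }
      list(cohort = cohort, features = features, eval = eval)
    },
    error = function(e) {
      note("stage failed: ", conditionMessage(e))
      finish("failed", e)
      stop(e)
    }
  )
  finish("complete")
  result$manifest <- manifest
  invisible(result)
}

# Deterministic hash of a configuration: MD5 of its canonical JSON dump.
config_hash <- function(config) {
  dump <- jsonlite::serializeJSON(
    lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  )
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(dump), tmp)
  unname(tools::md5sum(tmp))
}

#' Plot one subject's paired recording
#'
#' @param record One-row cohort tibble.
#' @param minutes Portion of the recording to draw (default: first 20 min).
#' @return A ggplot object with both channels over time.
#' @export
plot_subject <- function(record, minutes = 20) {
  fs <- record$fs[1]
  n <- min(length(record$fhr[[1]]), round(minutes * 60 * fs))
  df <- tibble::tibble(
    time_min = (seq_len(n) - 1) / fs / 60,
    fetal = record$fhr[[1]][seq_len(n)],
    maternal = record$mhr[[1]][seq_len(n)]
  )
  df <- tidyr::pivot_longer(df, -"time_min",
    names_to = "channel", values_to = "bpm"
  )
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$time_min, y = .data$bpm,
      colour = .data$channel
    )
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Time (min)", y = "Heart rate (bpm)",
      title = paste0(
        record$subject_id[1], " (", record$group[1],
        ", pH ", round(record$ph[1], 2), ")"
      )
    ) +
    ggplot2::theme_minimal()
}
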