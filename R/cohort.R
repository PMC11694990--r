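#' Configuration for a synthetic maternal-fetal cohort
#'
#' Captures the study conditions the generator emulates: 61 labouring women
#' (7 acidemic, 54 non-acidemic) monitored at 4 Hz for roughly the last two
#' hours before delivery, with occasional sample losses in the maternal
#' channel. Group membership follows the umbilical arterial pH rule
#' (acidemic iff pH < 7.15).
#'
#' @param n_nonacidemic,n_acidemic Number of subjects per group.
#' @param fs Sampling rate in Hz.
#' @param duration_min Nominal recording duration in minutes; each subject's
#'   actual duration is drawn uniformly from
#'   `[duration_min - jitter_min, duration_min]`, reflecting recordings that
#'   stop slightly short of the full window.
#' @param jitter_min Per-subject duration jitter in minutes.
#' @param effect_size Dimensionless acidemia effect, >= 0. At 0 the two
#'   groups are exchangeable. Positive values scale the acidemic fetal
#'   fast-fluctuation standard deviation by `1 / (1 + effect_size)` (reduced
#'   complexity) and the acidemic maternal-to-fetal coupling by
#'   `1 + effect_size` (stronger dependence on the mother).
#' @param coupling_nonacidemic,coupling_acidemic Baseline maternal-to-fetal
#'   coupling gain per group, before the `effect_size` scaling.
#' @param maternal_loss_fraction Expected fraction of maternal samples lost,
#'   in `[0, 1)`.
#' @param artifacts_per_hour Expected number of brief out-of-band artifact
#'   spikes injected per hour in each channel.
#' @param fhr_band Physiologic band (bpm) the generated fetal series is kept
#'   in, artifacts excepted.
#' @param seed Integer seed for the cohort's random stream.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_nonacidemic = 54L, n_acidemic = 7L, fs = 4,
                          duration_min = 120, jitter_min = 2,
                          effect_size = 1,
                          coupling_nonacidemic = 0.2,
                          coupling_acidemic = 0.2,
                          maternal_loss_fraction = 1e-4,
                          artifacts_per_hour = 1,
                          fhr_band = c(60, 200),
                          seed = 1L) {
  assert_scalar_number(n_nonacidemic, "n_nonacidemic", lower = 0)
  assert_scalar_number(n_acidemic, "n_acidemic", lower = 0)
  assert_scalar_number(fs, "fs")
  if (fs <= 0) stop_bad("`fs` must be > 0.")
  assert_scalar_number(duration_min, "duration_min")
  if (duration_min <= 0) stop_bad("`duration_min` must be > 0.")
  assert_scalar_number(jitter_min, "jitter_min", lower = 0)
  assert_scalar_number(effect_size, "effect_size", lower = 0)
  assert_scalar_number(coupling_nonacidemic, "coupling_nonacidemic")
  assert_scalar_number(coupling_acidemic, "coupling_acidemic")
  assert_scalar_number(maternal_loss_fraction, "maternal_loss_fraction",
    lower = 0
  )
  if (maternal_loss_fraction >= 1) {
    stop_bad("`maternal_loss_fraction` must be < 1.")
  }
  assert_scalar_number(artifacts_per_hour, "artifacts_per_hour", lower = 0)
  stopifnot(length(fhr_band) == 2L, fhr_band[1] < fhr_band[2])
  structure(
    list(
      n_nonacidemic = as.integer(n_nonacidemic),
      n_acidemic = as.integer(n_acidemic),
      fs = fs, duration_min = duration_min, jitter_min = jitter_min,
      effect_size = effect_size,
      coupling_nonacidemic = coupling_nonacidemic,
      coupling_acidemic = coupling_acidemic,
      maternal_loss_fraction = maternal_loss_fraction,
      artifacts_per_hour = artifacts_per_hour,
      fhr_band = fhr_band,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Slow baseline wander: a mixture of sinusoids with periods of at least
# 2 minutes, so it lands in the trend component of the moving-average
# decomposition.
slow_trend <- function(n, fs, n_components = 3L, amp_range = c(1, 4),
                       period_range_min = c(2, 20)) {
  t <- seq_len(n) / fs
  out <- numeric(n)
  for (i in seq_len(n_components)) {
    period <- runif(1, period_range_min[1], period_range_min[2]) * 60
    amp <- runif(1, amp_range[1], amp_range[2])
    phase <- runif(1, 0, 2 * pi)
    out <- out + amp * sin(2 * pi * t / period + phase)
  }
  out
}

# Stationary AR(1) noise with lag-1 coefficient `phi` and marginal sd
# `sigma`.
ar1_noise <- function(n, sigma, phi = 0.95) {
  innov_sd <- sigma * sqrt(1 - phi^2)
  as.numeric(
    stats::arima.sim(list(ar = phi), n = n, sd = innov_sd)
  )
}

# Transient accelerations/decelerations: Gaussian-shaped bumps 15-60 s wide.
event_bumps <- function(n, fs, rate_per_hour = 10, accel_prob = 0.6) {
  hours <- n / fs / 3600
  n_events <- stats::rpois(1, rate_per_hour * hours)
  out <- numeric(n)
  if (n_events == 0L) return(out)
  t <- seq_len(n)
  for (i in seq_len(n_events)) {
    center <- runif(1, 1, n)
    width_s <- runif(1, 15, 60)
    sd_samp <- width_s * fs / 4 # +/- 2 sd spans the nominal width
    amp <- runif(1, 10, 25) * if (runif(1) < accel_prob) 1 else -1
    out <- out + amp * exp(-0.5 * ((t - center) / sd_samp)^2)
  }
  out
}

# Brief out-of-band spikes emulating acquisition artifacts; runs of 1-8
# samples forced outside the physiologic band.
inject_artifacts <- function(x, fs, rate_per_hour, band) {
  hours <- length(x) / fs / 3600
  n_events <- stats::rpois(1, rate_per_hour * hours)
  for (i in seq_len(n_events)) {
    len <- sample.int(8L, 1L)
    start <- sample.int(max(length(x) - len, 1L), 1L)
    value <- if (runif(1) < 0.5) band[1] - runif(1, 10, 30) else {
      band[2] + runif(1, 10, 40)
    }
    x[start:(start + len - 1L)] <- value
  }
  x
}

#' Generate one synthetic subject
#'
#' Simulates a paired fetal/maternal heart-rate recording. Both channels are
#' built as baseline + slow sinusoid-mixture trend + AR(1) fast noise; the
#' fetal channel adds transient acceleration/deceleration bumps and a lagged
#' maternal-to-fetal coupling term. In the acidemic group the fetal
#' fast-noise standard deviation is shrunk and the coupling gain amplified,
#' both proportionally to `config$effect_size`, emulating the reduced
#' heart-rate complexity and the stronger dependence on the mother reported
#' in pathological labours.
#'
#' @param config A [cohort_config()].
#' @param group `"acidemic"` or `"nonacidemic"`.
#' @param subject_id Identifier stored in the record.
#' @param seed Integer seed for this subject's random stream.
#' @return A one-row tibble (`subject_id`, `group`, `ph`, `duration_min`,
#'   `fs`, `origin`, and list-columns `fhr`, `mhr` holding the sampled
#'   series; maternal gaps are `NA`).
#' @export
generate_subject <- function(config, group, subject_id = "s1",
                             seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% c("acidemic", "nonacidemic")) {
    stop_bad("`group` must be \"acidemic\" or \"nonacidemic\".")
  }
  set.seed(seed)
  fs <- config$fs
  duration <- config$duration_min -
    if (config$jitter_min > 0) runif(1, 0, config$jitter_min) else 0
  n <- round(duration * 60 * fs)

  eff <- config$effect_size
  acid <- group == "acidemic"
  coupling <- if (acid) config$coupling_acidemic * (1 + eff) else {
    config$coupling_nonacidemic
  }
  fhr_fast_sd <- if (acid) 6 / (1 + eff) else 6

  # maternal channel: ~80 bpm baseline, slow wander, AR(1) variability
  mhr_base <- rnorm(1, 80, 5)
  mhr <- mhr_base + slow_trend(n, fs, amp_range = c(1, 3)) +
    ar1_noise(n, sigma = 3)

  # fetal channel: ~140 bpm baseline + trend + events + fast noise + coupling
  fhr_base <- rnorm(1, 140, 8)
  lag_samp <- round(2 * fs) # maternal influence felt ~2 s later
  mhr_centered <- mhr - mean(mhr)
  mhr_lagged <- c(rep(mhr_centered[1], lag_samp),
                  mhr_centered[seq_len(n - lag_samp)])
  fhr <- fhr_base + slow_trend(n, fs, amp_range = c(1, 4)) +
    event_bumps(n, fs) + ar1_noise(n, sigma = fhr_fast_sd) +
    coupling * mhr_lagged
  fhr <- pmin(pmax(fhr, config$fhr_band[1]), config$fhr_band[2])
  mhr <- pmin(pmax(mhr, 40), 150)

  fhr <- inject_artifacts(fhr, fs, config$artifacts_per_hour, config$fhr_band)
  mhr <- inject_missing(mhr, config$maternal_loss_fraction)

  ph <- if (acid) runif(1, 7.00, 7.14) else runif(1, 7.16, 7.37)
  tibble::tibble(
    subject_id = subject_id, group = group, ph = ph,
    duration_min = duration, fs = fs, origin = "original",
    fhr = list(fhr), mhr = list(mhr)
  )
}

#' Mark contiguous runs of samples as missing
#'
#' Emulates acquisition dropouts: short contiguous runs (1-4 samples) are
#' replaced with `NA` until the expected missing fraction matches
#' `loss_fraction`. Uses the current random stream, so gap positions are
#' reproducible under a seed set by the caller.
#'
#' @param series Numeric vector.
#' @param loss_fraction Target fraction of missing samples, in `[0, 1)`.
#' @return `series` with `NA` gap markers.
#' @export
inject_missing <- function(series, loss_fraction) {
  assert_scalar_number(loss_fraction, "loss_fraction", lower = 0)
  if (loss_fraction >= 1) stop_bad("`loss_fraction` must be < 1.")
  if (loss_fraction == 0 || length(series) == 0L) return(series)
  n <- length(series)
  target <- loss_fraction * n
  lost <- 0
  while (lost < target) {
    # short dropouts (1-4 samples), trimmed so the total lands on target
    len <- min(sample.int(4L, 1L), max(1, round(target - lost)))
    start <- sample.int(max(n - len, 1L), 1L)
    idx <- start:(start + len - 1L)
    lost <- lost + sum(!is.na(series[idx]))
    series[idx] <- NA_real_
  }
  series
}

#' Generate a synthetic cohort
#'
#' Draws `n_nonacidemic + n_acidemic` subjects from [generate_subject()],
#' with per-subject seeds derived deterministically from `config$seed` so
#' the cohort is reproducible bit-for-bit.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject (see [generate_subject()]).
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_nonacidemic = 2, n_acidemic = 2,
#'   duration_min = 30, seed = 7
#' ))
#' cohort$group
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(
    rep("nonacidemic", config$n_nonacidemic),
    rep("acidemic", config$n_acidemic)
  )
  ids <- sprintf("s%02d", seq_along(groups))
  purrr::map2_dfr(ids, groups, function(id, gr) {
    generate_subject(config, gr, subject_id = id,
                     seed = derive_seed(config$seed, id))
  })
}

#' Write / read a cohort as per-subject CSV files
#'
#' Each subject is stored as `<subject_id>.csv` with columns `time_s`,
#' `fhr_bpm`, `mhr_bpm` (missing samples as empty cells), alongside a
#' `manifest.csv` (subject_id, ph, group, duration_min, fs, seed).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param seed Seed recorded in the manifest.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a cohort tibble.
#' @export
write_cohort <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::pwalk(cohort, function(subject_id, fs, fhr, mhr, ...) {
    readr::write_csv(
      tibble::tibble(
        time_s = (seq_along(fhr) - 1L) / fs,
        fhr_bpm = fhr, mhr_bpm = mhr
      ),
      file.path(dir, paste0(subject_id, ".csv")), na = ""
    )
  })
  manifest <- dplyr::select(
    cohort, "subject_id", "ph", "group", "duration_min", "fs", "origin"
  )
  manifest$seed <- seed
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_csv(
    file.path(dir, "manifest.csv"), show_col_types = FALSE
  )
  sig <- purrr::map(manifest$subject_id, function(id) {
    readr::read_csv(file.path(dir, paste0(id, ".csv")),
      show_col_types = FALSE
    )
  })
  manifest$fhr <- purrr::map(sig, "fhr_bpm")
  manifest$mhr <- purrr::map(sig, "mhr_bpm")
  tibble::as_tibble(manifest)
}
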