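#' Moving-average trend configuration
#'
#' @param window_samples Odd window length for the centered moving average
#'   (default 17, i.e. the 8 samples before and after the smoothed sample; at
#'   4 Hz this is a 2 s real-time delay).
#' @param fs Sampling rate in Hz (default 4).
#' @return A list of class `trend_config`.
#' @export
trend_config <- function(window_samples = 17L, fs = 4) {
  assert_scalar_number(window_samples, "window_samples", lower = 3)
  if (window_samples %% 2 == 0) stop_bad("`window_samples` must be odd.")
  assert_scalar_number(fs, "fs")
  if (fs <= 0) stop_bad("`fs` must be > 0.")
  structure(
    list(window_samples = as.integer(window_samples), fs = fs),
    class = "trend_config"
  )
}

#' Clean a heart-rate series
#'
#' Applies the standard cardiotocography artifact rules: samples below
#' `band[1]` bpm, above `band[2]` bpm, or differing from their predecessor by
#' more than `max_diff` bpm are invalidated, together with any pre-marked
#' `NA` gaps. Invalid runs lasting at most `max_gap_s` seconds are filled by
#' linear interpolation between the surrounding valid samples; longer runs
#' are filled by replicating the immediately preceding valid segment of
#' equal length (or, when the gap sits at the start of the recording, the
#' following one). Because a replacement can create a fresh out-of-band step
#' at its boundary, the rules are re-applied until none fires, up to
#' `max_passes` passes.
#'
#' @param series Numeric vector in bpm, possibly with `NA` gaps.
#' @param fs Sampling rate (Hz).
#' @param band Valid range in bpm (default `c(60, 200)`).
#' @param max_diff Largest allowed beat-to-beat difference in bpm
#'   (default 25).
#' @param max_gap_s Longest gap filled by interpolation, in seconds
#'   (default 2).
#' @param max_passes Maximum number of rule/repair passes (default 5).
#' @return A numeric vector of the same length with no invalid samples.
#' @examples
#' clean_heart_rate(c(140, 140, 250, 140), fs = 4)
#' @export
clean_heart_rate <- function(series, fs, band = c(60, 200), max_diff = 25,
                             max_gap_s = 2, max_passes = 5L) {
  if (length(series) < 2L) stop_bad("`series` must have at least 2 samples.")
  if (all(is.na(series))) stop_bad("`series` has no valid samples.")
  max_gap <- max_gap_s * fs

  for (pass in seq_len(max_passes)) {
    bad <- is.na(series) | series < band[1] | series > band[2]
    d <- abs(diff(series))
    jump <- c(FALSE, !is.na(d) & d > max_diff)
    # a jump implicates the later sample unless it is a return from an
    # already-invalid one
    bad <- bad | (jump & !c(FALSE, bad[-length(bad)]))
    if (!any(bad)) break
    if (all(bad)) stop_bad("`series` has no valid samples.")
    series <- fill_invalid_runs(series, bad, max_gap)
  }
  series
}

# Fill runs of invalid samples: interpolate short runs, replicate a
# neighboring valid block for long ones.
fill_invalid_runs <- function(series, bad, max_gap) {
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]
    e <- ends[i]
    len <- e - s + 1L
    left <- s - 1L
    right <- e + 1L
    if (len <= max_gap) {
      if (left >= 1L && right <= length(series)) {
        series[s:e] <- series[left] +
          (series[right] - series[left]) * seq_len(len) / (len + 1L)
        next
      }
      if (left >= 1L) {
        series[s:e] <- series[left]
        next
      }
      if (right <= length(series)) {
        series[s:e] <- series[right]
        next
      }
    } else {
      if (left >= len) {
        series[s:e] <- series[(s - len):(s - 1L)]
        next
      }
      if (right + len - 1L <= length(series)) {
        series[s:e] <- series[right:(right + len - 1L)]
        next
      }
      # degenerate: neither side offers a full block; hold the nearest value
      series[s:e] <- if (left >= 1L) series[left] else series[right]
    }
  }
  series
}

#' Shift a maternal heart-rate series into the fetal scale
#'
#' Adds exactly 50 bpm to every sample, the scale conversion that brings
#' typical maternal rates into the band used by the artifact rules.
#'
#' @param series Numeric vector in bpm.
#' @return The shifted series.
#' @examples
#' shift_mhr(c(70, 80))
#' @export
shift_mhr <- function(series) series + 50

#' Align a fetal/maternal pair to a common duration
#'
#' Both series are truncated at the tail to the length of the shorter one,
#' standardizing the simultaneous segment grid.
#'
#' @param fhr,mhr Numeric vectors.
#' @return A list with elements `fhr` and `mhr` of equal length.
#' @export
align_pair <- function(fhr, mhr) {
  if (length(fhr) == 0L || length(mhr) == 0L) {
    stop_bad("both series must be non-empty.")
  }
  n <- min(length(fhr), length(mhr))
  list(fhr = fhr[seq_len(n)], mhr = mhr[seq_len(n)])
}

#' Centered moving-average trend
#'
#' The trend at sample `t` is the mean of the `window_samples` values
#' centered at `t`. Only samples with a full window are defined, so
#' `(window_samples - 1) / 2` samples are lost at each end of the series.
#'
#' @param series Numeric vector.
#' @param cfg A [trend_config()].
#' @return A numeric vector of length
#'   `length(series) - window_samples + 1`, with attribute `offset` giving
#'   the number of samples dropped at each end.
#' @export
moving_average_trend <- function(series, cfg = trend_config()) {
  stopifnot(inherits(cfg, "trend_config"))
  w <- cfg$window_samples
  if (length(series) < w) {
    stop_bad("`series` must have at least window_samples = ", w, " samples.")
  }
  half <- (w - 1L) %/% 2L
  sm <- stats::filter(series, rep(1 / w, w), sides = 2)
  structure(as.numeric(sm[(half + 1L):(length(series) - half)]),
    offset = half
  )
}

#' Decompose a series into trend and residual
#'
#' The residual is the pointwise difference between the original series and
#' its centered moving-average trend on the trend's support, so
#' `trend + residual` reconstructs the original exactly there. The trend
#' captures slow baseline fluctuations, the residual the fast variability.
#'
#' @inheritParams moving_average_trend
#' @return A tibble with columns `sample` (index into the original series),
#'   `raw`, `trend` and `residual`.
#' @export
decompose_trend <- function(series, cfg = trend_config()) {
  trend <- moving_average_trend(series, cfg)
  half <- attr(trend, "offset")
  idx <- (half + 1L):(length(series) - half)
  tibble::tibble(
    sample = idx,
    raw = series[idx],
    trend = as.numeric(trend),
    residual = series[idx] - as.numeric(trend)
  )
}

slot_labels <- function() {
  paste0(
    rep(c("h1", "h2"), each = 6L), "-",
    rep(letters[1:6], times = 2L)
  )
}

#' Segment a series into labeled 10-minute windows
#'
#' Splits a series into consecutive non-overlapping nominal 10-minute
#' windows labeled `h1-a` .. `h2-f`, anchored at the recording end so that
#' `h2-f` is always the last 10 minutes before the recording stops. When the
#' recording is shorter than two hours the partial window falls at the
#' start; it is kept only if strictly longer than `min_minutes`.
#'
#' @param series Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param seg_minutes Nominal window length in minutes (default 10).
#' @param min_minutes Minimum data, in minutes, a partial window must exceed
#'   to be kept (default 5).
#' @return A tibble with one row per kept window: `hour`, `slot`, `label`,
#'   `start`, `end` (sample indices), `n_samples`, `is_partial`, and a
#'   list-column `samples`. The number of discarded windows is stored in
#'   attribute `n_discarded`.
#' @export
segment_series <- function(series, fs, seg_minutes = 10, min_minutes = 5) {
  if (length(series) == 0L) stop_bad("`series` must be non-empty.")
  if (fs <= 0) stop_bad("`fs` must be > 0.")
  seg_len <- as.integer(round(seg_minutes * 60 * fs))
  min_len <- min_minutes * 60 * fs
  n <- length(series)

  # full windows counted backwards from the end, then a leading partial
  ends <- seq.int(n, by = -seg_len, length.out = n %/% seg_len)
  starts <- ends - seg_len + 1L
  rem <- n %% seg_len
  if (rem > 0L) {
    starts <- c(starts, 1L)
    ends <- c(ends, rem)
  }
  # starts/ends ordered last-window-first; labels assigned from the end
  labels <- rev(slot_labels())
  keep <- logical(length(starts))
  lab <- character(length(starts))
  for (j in seq_along(starts)) {
    len_j <- ends[j] - starts[j] + 1L
    keep[j] <- j <= length(labels) && len_j > min_len
    lab[j] <- if (j <= length(labels)) labels[j] else NA_character_
  }
  out <- tibble::tibble(
    label = lab,
    start = as.integer(starts), end = as.integer(ends),
    n_samples = as.integer(ends - starts + 1L),
    is_partial = (ends - starts + 1L) < seg_len
  )[keep, ]
  out <- out[order(out$start), ]
  out$hour <- substr(out$label, 1, 2)
  out$slot <- substr(out$label, 4, 4)
  out$samples <- purrr::map2(out$start, out$end, function(s, e) series[s:e])
  out <- out[, c(
    "hour", "slot", "label", "start", "end", "n_samples",
    "is_partial", "samples"
  )]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Preprocess one subject end to end
#'
#' Runs the per-subject cleaning chain in the pipeline's canonical order:
#' the maternal series is shifted by +50 bpm and then cleaned, the fetal
#' series is cleaned, the pair is aligned to the shorter duration, each
#' channel is decomposed into trend and residual, and each component is
#' segmented into labeled 10-minute windows.
#'
#' @param record A one-row cohort tibble (see [generate_subject()]).
#' @param cfg A [trend_config()].
#' @return A list with `segments` (tibble: `channel`, `component`, `hour`,
#'   `slot`, `label`, `samples` list-column), `series` (tibble: `channel`,
#'   `component`, `samples` list-column with the full decomposed series),
#'   `loss` (named maternal/fetal missing fractions before cleaning) and
#'   `n_discarded` segment count.
#' @export
preprocess_subject <- function(record, cfg = trend_config()) {
  fhr_raw <- record$fhr[[1]]
  mhr_raw <- record$mhr[[1]]
  fs <- record$fs[1]
  loss <- c(
    fetal = fraction_lost(fhr_raw),
    maternal = fraction_lost(mhr_raw)
  )
  fhr <- clean_heart_rate(fhr_raw, fs)
  mhr <- clean_heart_rate(shift_mhr(mhr_raw), fs)
  pair <- align_pair(fhr, mhr)

  discarded <- 0L
  series_tbl <- list()
  seg_tbl <- list()
  for (channel in c("fetal", "maternal")) {
    x <- if (channel == "fetal") pair$fhr else pair$mhr
    dec <- decompose_trend(x, cfg)
    for (component in c("trend", "residual")) {
      comp <- dec[[component]]
      series_tbl[[paste(channel, component)]] <- tibble::tibble(
        channel = channel, component = component, samples = list(comp)
      )
      segs <- segment_series(comp, fs)
      discarded <- discarded + attr(segs, "n_discarded")
      segs$channel <- channel
      segs$component <- component
      seg_tbl[[paste(channel, component)]] <- segs
    }
  }
  segments <- dplyr::bind_rows(seg_tbl)
  segments <- segments[, c(
    "channel", "component", "hour", "slot", "label",
    "start", "end", "n_samples", "is_partial", "samples"
  )]
  list(
    segments = tibble::as_tibble(segments),
    series = dplyr::bind_rows(series_tbl),
    loss = loss,
    n_discarded = discarded / 4L # same grid in all four channel-components
  )
}
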