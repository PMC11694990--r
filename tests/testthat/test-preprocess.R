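test_that("artifact rules invalidate and interpolate short gaps", {
  out <- clean_heart_rate(c(140, 140, 250, 140), fs = 4)
  expect_equal(out, c(140, 140, 140, 140))

  clean <- 120 + 10 * sin(seq(0, 4 * pi, length.out = 200))
  expect_equal(clean_heart_rate(clean, fs = 4), clean)

  # NA gap of 2 samples: linear interpolation between neighbors
  x <- c(100, 100, NA, NA, 106, 106)
  expect_equal(clean_heart_rate(x, fs = 4), c(100, 100, 102, 104, 106, 106))
})

test_that("long invalid runs are filled by replicating the previous block", {
  lead <- 100 + (1:12) # 12 valid samples
  x <- c(lead, rep(300, 12), 100 + (1:12))
  out <- clean_heart_rate(x, fs = 4)
  expect_equal(out[13:24], lead)

  # gap at the recording start falls back to the following block
  y <- c(rep(NA, 12), 100 + (1:24))
  out2 <- clean_heart_rate(y, fs = 4)
  expect_equal(out2[1:12], 100 + (1:12))
})

test_that("cleaned output respects band and jump invariants", {
  set.seed(4)
  x <- 140 + cumsum(rnorm(2000, 0, 3))
  x[sample(2000, 20)] <- 230
  x[sample(2000, 20)] <- 40
  out <- clean_heart_rate(x, fs = 4)
  expect_false(anyNA(out))
  expect_true(all(out >= 60 & out <= 200))
})

test_that("shift_mhr adds exactly 50 and is invertible", {
  expect_equal(shift_mhr(c(70, 80)), c(120, 130))
  expect_equal(shift_mhr(numeric(0)), numeric(0))
  x <- rnorm(10, 80)
  expect_equal(shift_mhr(x) - 50, x)
})

test_that("fraction_lost counts missing over total", {
  expect_equal(fraction_lost(rep(1, 100)), 0)
  expect_equal(fraction_lost(c(rep(1, 99), NA)), 0.01)
  expect_equal(fraction_lost(rep(NA_real_, 5)), 1)
  expect_error(fraction_lost(numeric(0)), "non-empty")
})

test_that("align_pair truncates the tail to the shorter series", {
  p <- align_pair(rnorm(28800), rnorm(28700))
  expect_length(p$fhr, 28700)
  expect_length(p$mhr, 28700)
  a <- 1:10 + 0
  p2 <- align_pair(a, c(5, 6, 7))
  expect_equal(p2$fhr, c(1, 2, 3))
  expect_error(align_pair(numeric(0), 1), "non-empty")
})

test_that("centered moving average is exact on constants and ramps", {
  cfg <- trend_config(window_samples = 17)
  expect_equal(
    as.numeric(moving_average_trend(rep(3.5, 50), cfg)), rep(3.5, 34)
  )
  ramp <- 2 * (1:100) + 1
  tr <- moving_average_trend(ramp, cfg)
  expect_equal(as.numeric(tr), ramp[9:92], tolerance = 1e-12)
  expect_length(tr, 100 - 16)
  expect_equal(attr(tr, "offset"), 8) # 8 samples / 4 Hz = 2 s delay
  expect_error(moving_average_trend(1:10, cfg), "window_samples")
  expect_error(trend_config(window_samples = 16), "odd")
})

test_that("trend + residual reconstructs the original exactly", {
  set.seed(9)
  x <- 140 + arima.sim(list(ar = 0.95), 500, sd = 2)
  dec <- decompose_trend(as.numeric(x))
  expect_equal(dec$trend + dec$residual, dec$raw, tolerance = 0)
  expect_equal(dec$raw, as.numeric(x)[dec$sample])
  # constant series has (numerically) zero residual
  expect_equal(decompose_trend(rep(7, 60))$residual, rep(0, 44),
    tolerance = 1e-12
  )
})

test_that("smoothing shifts power from residual to trend for AR noise", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- as.numeric(arima.sim(list(ar = 0.5), 400, sd = 1))
    dec <- decompose_trend(x)
    var(dec$residual) > var(dec$trend)
  }, logical(1))
  expect_true(mean(hits) > 0.9)
})

test_that("segmentation is anchored at the recording end", {
  fs <- 4
  full <- segment_series(rnorm(120 * 60 * fs), fs)
  expect_equal(nrow(full), 12)
  expect_equal(attr(full, "n_discarded"), 0)
  expect_equal(full$label[12], "h2-f")
  expect_false(any(full$is_partial))

  s117 <- segment_series(rnorm(117 * 60 * fs), fs)
  expect_equal(nrow(s117), 12) # 7-min leading partial kept
  expect_equal(sum(s117$is_partial), 1)
  expect_equal(s117$label[1], "h1-a")
  expect_equal(s117$n_samples[1], 7 * 60 * fs)

  s114 <- segment_series(rnorm(114 * 60 * fs), fs)
  expect_equal(nrow(s114), 11) # 4-min partial discarded
  expect_equal(attr(s114, "n_discarded"), 1)
})

test_that("kept segments tile the input without overlap", {
  x <- rnorm(115 * 60 * 4)
  segs <- segment_series(x, 4)
  expect_true(all(diff(segs$start) > 0))
  expect_true(all(segs$start[-1] == segs$end[-nrow(segs)] + 1))
  spans <- unlist(segs$samples)
  expect_equal(spans, x[segs$start[1]:segs$end[nrow(segs)]])
})

test_that("preprocess_subject yields an identical grid in all components", {
  rec <- small_cohort(seed = 31, n_non = 1, n_acid = 0, duration_min = 45)
  prep <- preprocess_subject(rec[1, ])
  grids <- split(prep$segments$label, paste(
    prep$segments$channel, prep$segments$component
  ))
  expect_length(unique(lapply(grids, identity)), 1)
  expect_named(prep$loss, c("fetal", "maternal"))
})
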