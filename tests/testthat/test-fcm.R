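test_that("fit_fcm counts contexts and blocks by hand-checkable sliding", {
  cfg <- fcm_config(k = 1, d = 1, alphabet_size = 2)
  m <- fit_fcm(c(0L, 1L, 0L, 1L, 0L, 1L), cfg) # "ABABAB"
  counts <- fcm_counts(m)
  expect_equal(counts$count[counts$context == "0" & counts$block == "1"], 3)
  expect_equal(counts$count[counts$context == "1" & counts$block == "0"], 2)
  expect_equal(sum(counts$count), 5) # len - k - d + 1

  # constant sequence: a single (context, block) pair
  cfg2 <- fcm_config(k = 2, d = 3, alphabet_size = 4)
  m2 <- fit_fcm(rep(2L, 20), cfg2)
  c2 <- fcm_counts(m2)
  expect_equal(nrow(c2), 1)
  expect_equal(c2$count, 20 - 2 - 3 + 1)

  expect_identical(
    fcm_counts(fit_fcm(c(0L, 1L, 1L, 0L, 1L), cfg)),
    fcm_counts(fit_fcm(c(0L, 1L, 1L, 0L, 1L), cfg))
  )
  expect_error(fit_fcm(c(0L, 1L), fcm_config(k = 2, d = 2)), "k \\+ d")
})

test_that("relative code length matches the brute-force oracle exhaustively", {
  # every x of length (k+d)..7 over alphabets 2 and 3, all k, d <= 2,
  # against fixed training sequences
  for (A in 2:3) {
    set.seed(A)
    y <- sample(0:(A - 1L), 40, replace = TRUE)
    for (k in 1:2) {
      for (d in 1:2) {
        cfg <- fcm_config(k = k, d = d, alphabet_size = A)
        m <- fit_fcm(y, cfg)
        for (len in (k + d):7) {
          xs <- all_sequences(len, A)
          for (i in seq_len(nrow(xs))) {
            x <- as.integer(xs[i, ])
            expect_equal(
              relative_code_length(x, m)$bits,
              oracle_code_length(x, y, k, d, A),
              tolerance = 1e-9
            )
          }
        }
      }
    }
  }
})

test_that("relative code length matches the oracle on random longer cases", {
  set.seed(99)
  for (r in 1:100) {
    A <- sample(2:3, 1)
    k <- sample(1:2, 1)
    d <- sample(1:2, 1)
    cfg <- fcm_config(k = k, d = d, alphabet_size = A)
    y <- sample(0:(A - 1L), sample(20:60, 1), replace = TRUE)
    x <- sample(0:(A - 1L), sample(8:30, 1), replace = TRUE)
    expect_equal(
      relative_code_length(x, fit_fcm(y, cfg))$bits,
      oracle_code_length(x, y, k, d, A),
      tolerance = 1e-9
    )
  }
})

test_that("code length is bounded by the incompressible ceiling", {
  set.seed(5)
  cfg <- fcm_config(k = 3, d = 2, alphabet_size = 4)
  m <- fit_fcm(sample(0:3, 500, replace = TRUE), cfg)
  for (r in 1:20) {
    x <- sample(0:3, sample(6:200, 1), replace = TRUE)
    cl <- relative_code_length(x, m)
    expect_lte(cl$bits, length(x) * log2(4) + 1e-9)
    expect_gte(cl$bits, 0)
  }
})

test_that("a predictive source drives NRC toward 0, independence toward 1", {
  cfg <- fcm_config(k = 2, d = 1, alphabet_size = 4, alpha = 1)
  periodic <- rep(c(0L, 1L, 2L, 3L), 1000)
  expect_lt(nrc(periodic, periodic, cfg), 0.1)

  set.seed(12)
  x <- sample(0:3, 3000, replace = TRUE)
  y <- sample(0:3, 3000, replace = TRUE)
  v <- nrc(x, y, cfg)
  expect_gt(v, 0.95)
  expect_lte(v, 1)
  # iid uniform bits/symbol within 5% of log2 A
  bits <- relative_code_length(x, fit_fcm(y, cfg))$bits
  expect_equal(bits / length(x), log2(4), tolerance = 0.05)
})

test_that("NRC is directional", {
  set.seed(3)
  cfg <- fcm_config(k = 2, d = 1, alphabet_size = 4)
  x <- rep(c(0L, 1L, 2L, 3L), 250)
  y <- x
  flip <- sample(1000, 300)
  y[flip] <- sample(0:3, 300, replace = TRUE)
  expect_false(isTRUE(all.equal(nrc(x, y, cfg), nrc(y, x, cfg))))
})

test_that("NRC stays in [0,1] and degrades monotonically with noise", {
  cfg <- fcm_config(k = 2, d = 2, alphabet_size = 4)
  noise_frac <- seq(0, 1, by = 0.125)
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rep(c(0L, 1L, 2L, 3L, 2L, 1L), 200)
    vals <- vapply(noise_frac, function(nf) {
      y <- x
      idx <- sample(length(y), round(nf * length(y)))
      y[idx] <- sample(0:3, length(idx), replace = TRUE)
      v <- nrc(x, y, cfg)
      expect_gte(v, 0)
      expect_lte(v, 1)
      v
    }, numeric(1))
    suppressWarnings(cor(noise_frac, vals, method = "spearman"))
  }, numeric(1))
  expect_gt(mean(rhos), 0.9)
})
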