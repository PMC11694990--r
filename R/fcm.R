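#' Extended-alphabet finite-context model configuration
#'
#' @param k Context order: number of symbols conditioning each prediction
#'   (default 6).
#' @param d Block depth: number of symbols predicted jointly per coding step
#'   (default 6).
#' @param alphabet_size Number of symbols in the quantized alphabet
#'   (default 20).
#' @param alpha Additive (Laplace) smoothing pseudo-count spread over the
#'   `alphabet_size^d` block space (default 1).
#' @return A list of class `fcm_config`.
#' @export
fcm_config <- function(k = 6L, d = 6L, alphabet_size = 20L, alpha = 1) {
  assert_scalar_number(k, "k", lower = 1)
  assert_scalar_number(d, "d", lower = 1)
  assert_scalar_number(alphabet_size, "alphabet_size", lower = 2)
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0) stop_bad("`alpha` must be > 0.")
  structure(
    list(
      k = as.integer(k), d = as.integer(d),
      alphabet_size = as.integer(alphabet_size), alpha = alpha
    ),
    class = "fcm_config"
  )
}

# Integer id of every length-`width` window of a 0-based symbol vector,
# most-significant symbol first. Window starting at i has
# id = sum_j s[i + j] * A^(width - 1 - j). Returned as doubles; callers keep
# A^width * A^k below 2^53 so combined keys stay exact.
window_ids <- function(codes, width, A) {
  n <- length(codes)
  if (n < width) return(numeric(0))
  if (width == 1L) return(as.numeric(codes))
  E <- embed(as.numeric(codes), width) # row i: codes[i+width-1], ..., codes[i]
  drop(E %*% A^(seq_len(width) - 1))
}

check_codes <- function(x, A, name) {
  x <- as.integer(x)
  if (anyNA(x) || any(x < 0L) || any(x >= A)) {
    stop_bad("`", name, "` must hold integer codes in [0, ", A, ").")
  }
  x
}

#' Fit an extended-alphabet finite-context model
#'
#' Slides over the training sequence `y` with step 1 and, at every position
#' with a full `k`-symbol context followed by a full `d`-symbol block,
#' increments the count of that (context, block) pair. The model depends on
#' `y` only; coding a second sequence against it yields the relative code
#' length behind the normalized relative compression.
#'
#' @param y Integer symbol codes in `[0, alphabet_size)` (e.g. from
#'   [quantize()]).
#' @param cfg An [fcm_config()].
#' @return An object of class `fcm_model` holding the sparse count table.
#' @examples
#' cfg <- fcm_config(k = 1, d = 1, alphabet_size = 2)
#' m <- fit_fcm(c(0L, 1L, 0L, 1L, 0L, 1L), cfg)
#' fcm_counts(m)
#' @export
fit_fcm <- function(y, cfg) {
  stopifnot(inherits(cfg, "fcm_config"))
  A <- cfg$alphabet_size
  y <- check_codes(y, A, "y")
  k <- cfg$k
  d <- cfg$d
  n_pos <- length(y) - k - d + 1L
  if (n_pos < 1L) {
    stop_bad("`y` must have at least k + d = ", k + d, " symbols.")
  }
  Ad <- A^d
  ctx <- window_ids(y, k, A)[seq_len(n_pos)]
  blk <- window_ids(y, d, A)[k + seq_len(n_pos)]
  key <- ctx * Ad + blk

  key_r <- rle(sort(key))
  ctx_r <- rle(sort(ctx))
  structure(
    list(
      key = key_r$values, key_n = key_r$lengths,
      ctx = ctx_r$values, ctx_n = ctx_r$lengths,
      config = cfg, n_positions = n_pos
    ),
    class = "fcm_model"
  )
}

# Exact-match lookup of `keys` in the sorted vector `sorted` with per-key
# counts `counts`; absent keys count 0.
lookup_counts <- function(keys, sorted, counts) {
  idx <- findInterval(keys, sorted)
  out <- numeric(length(keys))
  hit <- idx > 0L
  hit[hit] <- sorted[idx[hit]] == keys[hit]
  out[hit] <- counts[idx[hit]]
  out
}

#' Counts stored in a finite-context model
#'
#' @param model An `fcm_model`.
#' @return A tibble with one row per observed (context, block) pair: the
#'   context symbols, the block symbols (both as dash-separated code strings)
#'   and the occurrence count.
#' @export
fcm_counts <- function(model) {
  stopifnot(inherits(model, "fcm_model"))
  cfg <- model$config
  A <- cfg$alphabet_size
  Ad <- A^cfg$d
  ctx_id <- floor(model$key / Ad)
  blk_id <- model$key - ctx_id * Ad
  decode <- function(id, width) {
    vapply(id, function(v) {
      digs <- integer(width)
      for (j in seq_len(width)) {
        digs[width - j + 1L] <- v %% A
        v <- v %/% A
      }
      paste(digs, collapse = "-")
    }, character(1))
  }
  tibble::tibble(
    context = decode(ctx_id, cfg$k),
    block = decode(blk_id, cfg$d),
    count = model$key_n
  )
}

#' Relative code length of a sequence under a finite-context model
#'
#' Codes `x` in consecutive non-overlapping `d`-symbol blocks after the first
#' `k` bootstrap symbols. Each block costs `-log2 P(block | context)` bits,
#' where the context is the `k` symbols immediately preceding the block
#' (contexts may straddle block boundaries) and
#' `P = (count + alpha) / (context_total + alpha * A^d)` with the counts taken
#' from `model`. Per-block cost is capped at `d * log2(A)` bits, and the `k`
#' bootstrap symbols plus any final partial block are charged `log2(A)` bits
#' per symbol, so the total never exceeds `length(x) * log2(A)`.
#'
#' @param x Integer symbol codes over the model's alphabet.
#' @param model An `fcm_model` fitted with [fit_fcm()].
#' @return A list of class `code_length` with `bits` (total code length) and
#'   `n_symbols` (`length(x)`).
#' @export
relative_code_length <- function(x, model) {
  stopifnot(inherits(model, "fcm_model"))
  cfg <- model$config
  A <- cfg$alphabet_size
  k <- cfg$k
  d <- cfg$d
  x <- check_codes(x, A, "x")
  n <- length(x)
  if (n < k + d) stop_bad("`x` must have at least k + d = ", k + d, " symbols.")
  Ad <- A^d
  log2A <- log2(A)

  starts <- seq.int(k + 1L, n - d + 1L, by = d)
  ctx <- window_ids(x, k, A)[starts - k]
  blk <- window_ids(x, d, A)[starts]
  cnt <- lookup_counts(ctx * Ad + blk, model$key, model$key_n)
  ctot <- lookup_counts(ctx, model$ctx, model$ctx_n)
  bits_blocks <- pmin(
    -log2((cnt + cfg$alpha) / (ctot + cfg$alpha * Ad)),
    d * log2A
  )
  n_flat <- k + (n - k) %% d # bootstrap + trailing partial block
  structure(
    list(bits = sum(bits_blocks) + n_flat * log2A, n_symbols = n),
    class = "code_length"
  )
}

#' Normalized relative compression of one symbol sequence given another
#'
#' NRC(x || y) = C(x || y) / (|x| log2 |A|), where C(x || y) is the code
#' length of `x` under a finite-context model trained exclusively on `y`
#' ([fit_fcm()], [relative_code_length()]). Values near 0 mean `y` describes
#' `x` almost completely; values near 1 mean `x` carries information `y`
#' cannot supply. The measure is directional: NRC(x || y) and NRC(y || x)
#' differ in general.
#'
#' @param x,y Integer symbol codes over a common alphabet.
#' @param cfg An [fcm_config()].
#' @return A single number in \[0, 1\].
#' @examples
#' cfg <- fcm_config(k = 2, d = 1, alphabet_size = 2)
#' s <- rep(c(0L, 1L), 100)
#' nrc(s, s, cfg) # self-similar: near 0
#' @export
nrc <- function(x, y, cfg) {
  cl <- relative_code_length(x, fit_fcm(y, cfg))
  cl$bits / (cl$n_symbols * log2(cfg$alphabet_size))
}
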