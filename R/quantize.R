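#' Fit a Lloyd-Max scalar quantizer
#'
#' Alternates the two Lloyd optimality conditions until the codebook is a
#' fixed point: (i) cell boundaries are midpoints of adjacent reconstruction
#' levels, (ii) each level is the mean of the training samples falling in its
#' cell. The result is a locally MSE-optimal scalar quantizer, the standard
#' choice for turning a continuous heart-rate component into a symbol stream
#' before finite-context modelling.
#'
#' Levels are initialized at the `L` equally spaced empirical quantiles of the
#' samples, which is deterministic and robust for the skewed distributions
#' heart-rate segments can show. A cell that empties during iteration has its
#' level re-seeded at the midpoint of its current boundaries.
#'
#' @param samples Numeric vector of training values (bpm); must contain at
#'   least `L` distinct values.
#' @param L Alphabet size (number of reconstruction levels), default 20.
#' @param tol Convergence tolerance on the largest level shift, in the units
#'   of `samples` (default 1e-6).
#' @param max_iter Maximum number of Lloyd iterations (default 500).
#' @return An object of class `lloyd_quantizer`: a list with `levels`
#'   (increasing reconstruction values), `boundaries` (`L - 1` strictly
#'   increasing thresholds), `alphabet_size`, `distortion` (final empirical
#'   MSE), `distortion_trace` (per-iteration MSE) and `iterations`.
#' @examples
#' q <- fit_lloyd_max(runif(1000), L = 4)
#' q$levels
#' @seealso [quantize()]
#' @export
fit_lloyd_max <- function(samples, L = 20L, tol = 1e-6, max_iter = 500L) {
  samples <- samples[!is.na(samples)]
  assert_scalar_number(L, "L", lower = 1)
  if (length(unique(samples)) < L) {
    stop_bad("`samples` must contain at least L = ", L, " distinct values.")
  }
  L <- as.integer(L)
  if (L == 1L) {
    out <- list(
      levels = mean(samples), boundaries = numeric(0), alphabet_size = 1L,
      distortion = mean((samples - mean(samples))^2),
      distortion_trace = mean((samples - mean(samples))^2), iterations = 0L
    )
    return(structure(out, class = "lloyd_quantizer"))
  }

  levels <- unname(quantile(samples, probs = (seq_len(L) - 0.5) / L, type = 7))
  if (any(diff(levels) <= 0)) {
    levels <- seq(min(samples), max(samples), length.out = L)
  }

  # Work on the sorted samples with cumulative sums: each cell is then a
  # contiguous run, so one iteration costs O(L log n) rather than O(n).
  xs <- sort(samples)
  n <- length(xs)
  cum1 <- c(0, cumsum(xs))
  cum2 <- c(0, cumsum(xs^2))
  lo <- xs[1L]
  hi <- xs[n]
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    boundaries <- (levels[-L] + levels[-1L]) / 2
    # quantize() sends a value equal to a boundary upward, so cell i ends at
    # the last sample strictly below boundary i
    pos <- c(0L, findInterval(boundaries, xs, left.open = TRUE), n)
    counts <- diff(pos)
    sums <- cum1[pos[-1L] + 1L] - cum1[pos[-(L + 1L)] + 1L]
    sumsq <- cum2[pos[-1L] + 1L] - cum2[pos[-(L + 1L)] + 1L]
    new_levels <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
    # empty cells: re-seed at the midpoint of the cell's boundaries
    if (anyNA(new_levels)) {
      b_ext <- c(lo, boundaries, hi)
      mid <- (b_ext[-length(b_ext)] + b_ext[-1L]) / 2
      new_levels[is.na(new_levels)] <- mid[is.na(new_levels)]
    }
    new_levels <- sort(new_levels)
    trace <- c(
      trace,
      sum(sumsq - 2 * new_levels * sums + counts * new_levels^2) / n
    )
    shift <- max(abs(new_levels - levels))
    levels <- new_levels
    if (shift < tol || iter >= max_iter) break
  }

  boundaries <- (levels[-L] + levels[-1L]) / 2
  pos <- c(0L, findInterval(boundaries, xs, left.open = TRUE), n)
  counts <- diff(pos)
  sums <- cum1[pos[-1L] + 1L] - cum1[pos[-(L + 1L)] + 1L]
  sumsq <- cum2[pos[-1L] + 1L] - cum2[pos[-(L + 1L)] + 1L]
  structure(
    list(
      levels = levels, boundaries = boundaries, alphabet_size = L,
      distortion = sum(sumsq - 2 * levels * sums + counts * levels^2) / n,
      distortion_trace = trace, iterations = iter
    ),
    class = "lloyd_quantizer"
  )
}

#' Map a real-valued series to quantizer symbols
#'
#' Each sample is assigned the index of its quantizer cell: values below the
#' first boundary map to symbol 0, values at or above the last boundary map
#' to symbol `L - 1`. The quantizer covers the whole real line, so any finite
#' input is representable; length is preserved.
#'
#' @param series Numeric vector to encode.
#' @param quantizer A `lloyd_quantizer` from [fit_lloyd_max()].
#' @return Integer vector of symbol codes in `[0, L)`, with attribute
#'   `alphabet_size`.
#' @examples
#' q <- fit_lloyd_max(runif(500), L = 4)
#' head(quantize(runif(10), q))
#' @export
quantize <- function(series, quantizer) {
  stopifnot(inherits(quantizer, "lloyd_quantizer"))
  codes <- findInterval(series, quantizer$boundaries)
  structure(as.integer(codes), alphabet_size = quantizer$alphabet_size)
}

#' Reconstruct sample values from symbol codes
#'
#' @param codes Integer codes as returned by [quantize()].
#' @param quantizer The fitted `lloyd_quantizer`.
#' @return Numeric vector of reconstruction levels.
#' @export
dequantize <- function(codes, quantizer) {
  stopifnot(inherits(quantizer, "lloyd_quantizer"))
  quantizer$levels[as.integer(codes) + 1L]
}

#' @export
print.lloyd_quantizer <- function(x, ...) {
  cat(
    "Lloyd-Max quantizer: ", x$alphabet_size, " levels in [",
    round(min(x$levels), 3), ", ", round(max(x$levels), 3),
    "], MSE ", signif(x$distortion, 4), ", ", x$iterations, " iterations\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a Lloyd-Max quantizer
#'
#' @param x A `lloyd_quantizer`.
#' @param ... Unused.
#' @return A tibble with one row per symbol: `symbol`, `level`, and the cell
#'   bounds `lower` / `upper` (infinite at the edges).
#' @export
tidy.lloyd_quantizer <- function(x, ...) {
  L <- x$alphabet_size
  tibble::tibble(
    symbol = seq_len(L) - 1L,
    level = x$levels,
    lower = c(-Inf, x$boundaries),
    upper = c(x$boundaries, Inf)
  )
}

#' Serialize a quantizer to JSON
#'
#' @param quantizer A `lloyd_quantizer`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
quantizer_to_json <- function(quantizer, path = NULL) {
  stopifnot(inherits(quantizer, "lloyd_quantizer"))
  js <- jsonlite::toJSON(
    list(
      levels = quantizer$levels,
      boundaries = quantizer$boundaries,
      alphabet_size = quantizer$alphabet_size
    ),
    digits = NA, auto_unbox = TRUE
  )
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
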