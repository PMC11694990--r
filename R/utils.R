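#' @importFrom rlang .data abort %||%
#' @importFrom stats quantile rnorm runif rbinom var sd cor predict
#' @importFrom utils head tail
NULL

# Internal: fail fast with a consistent message style.
stop_bad <- function(...) rlang::abort(paste0(...), class = "ctgcompress_error")

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad("`", name, "` must be a single finite number.")
  }
  if (x < lower || x > upper) {
    stop_bad("`", name, "` must be in [", lower, ", ", upper, "].")
  }
  invisible(x)
}

# Derive a reproducible child seed from a global seed and a stage label.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

#' Missing-sample marker helpers
#'
#' Gaps in a heart-rate series are represented as `NA` samples. These helpers
#' exist so the convention is explicit at call sites.
#'
#' @param series Numeric vector, possibly containing `NA` gap markers.
#' @return `is_gap()` returns a logical vector; `fraction_lost()` a single
#'   number in \[0, 1\]: the number of missing samples over the total number
#'   of samples.
#' @examples
#' fraction_lost(c(1, NA, 3, 4))
#' @export
fraction_lost <- function(series) {
  if (length(series) == 0L) stop_bad("`series` must be non-empty.")
  mean(is.na(series))
}

#' @rdname fraction_lost
#' @export
is_gap <- function(series) is.na(series)
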