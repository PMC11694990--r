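#' Serialize a heart-rate segment to bytes
#'
#' Deterministic one-byte-per-sample encoding used by the DEFLATE-based
#' measures: each sample is shifted by `offset`, rounded to the nearest
#' integer and clamped to \[0, 255\]. Heart-rate values in bpm fit the byte
#' range directly; zero-centered residual components should be passed with
#' `offset = 128` so negative fluctuations survive the clamp.
#'
#' @param samples Numeric vector (bpm or residual bpm).
#' @param offset Value added to every sample before rounding (default 0).
#' @return A raw vector of `length(samples)` bytes.
#' @examples
#' serialize_segment(c(140.4, 140.6))
#' @export
serialize_segment <- function(samples, offset = 0) {
  as.raw(pmin(255, pmax(0, round(samples + offset))))
}

deflate_bytes <- function(bytes) {
  length(memCompress(bytes, type = "gzip"))
}

#' Compression ratio of a segment
#'
#' Ratio between the serialized byte length of a segment and its length after
#' lossless compression: the number of times the original length has been
#' reduced. High values indicate high redundancy, i.e. low information
#' content. The backend is the zlib DEFLATE stream via [memCompress()] at its
#' fixed default settings, so values are comparable across runs.
#'
#' @param samples Numeric vector; compressed after [serialize_segment()].
#' @param offset Serialization offset, see [serialize_segment()].
#' @return A single positive number.
#' @examples
#' compression_ratio(rep(140, 2400)) # highly redundant
#' @export
compression_ratio <- function(samples, offset = 0) {
  if (length(samples) == 0L) stop_bad("`samples` must be non-empty.")
  b <- serialize_segment(samples, offset)
  length(b) / deflate_bytes(b)
}

#' Normalized compression distance between two segments
#'
#' NCD(x, y) = (C(xy) - min(C(x), C(y))) / max(C(x), C(y)), where C is the
#' compressed byte length of the serialization and `xy` the concatenation of
#' the two serialized segments in the order given. The value is near 0 for
#' segments that describe each other and near 1 for unrelated segments. The
#' pipeline always calls it in the fixed (fetal, maternal) order, as
#' swapping the arguments can change the concatenation and hence the value.
#'
#' @param x,y Numeric vectors.
#' @param offset Serialization offset applied to both segments.
#' @return A single number, normalized to be comparable across pairs
#'   (approximately in \[0, 1\]; slightly above 1 is possible for
#'   incompressible inputs).
#' @examples
#' set.seed(1)
#' a <- cumsum(rnorm(2000))
#' ncd(a, a) # self-distance: small
#' @export
ncd <- function(x, y, offset = 0) {
  if (length(x) == 0L || length(y) == 0L) {
    stop_bad("`x` and `y` must be non-empty.")
  }
  bx <- serialize_segment(x, offset)
  by <- serialize_segment(y, offset)
  cx <- deflate_bytes(bx)
  cy <- deflate_bytes(by)
  cxy <- deflate_bytes(c(bx, by))
  (cxy - min(cx, cy)) / max(cx, cy)
}
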