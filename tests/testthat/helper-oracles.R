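# Independent oracles kept deliberately naive: direct enumerations against
# which the vectorized implementations are checked.

# Brute-force relative code length: for each non-overlapping d-block of x
# after the first k symbols, count matching (context, block) and context
# occurrences by scanning y position by position, then sum the smoothed
# -log2 probabilities with the per-block cap. Bootstrap symbols and a
# trailing partial block cost log2(A) bits each.
oracle_code_length <- function(x, y, k, d, A, alpha = 1) {
  log2A <- log2(A)
  n <- length(x)
  bits <- 0
  pos <- k + 1L
  while (pos + d - 1L <= n) {
    ctx <- x[(pos - k):(pos - 1L)]
    blk <- x[pos:(pos + d - 1L)]
    cnt <- 0
    ctot <- 0
    for (i in seq_len(length(y) - k - d + 1L)) {
      yc <- y[i:(i + k - 1L)]
      yb <- y[(i + k):(i + k + d - 1L)]
      if (all(yc == ctx)) {
        ctot <- ctot + 1L
        if (all(yb == blk)) cnt <- cnt + 1L
      }
    }
    p <- (cnt + alpha) / (ctot + alpha * A^d)
    bits <- bits + min(-log2(p), d * log2A)
    pos <- pos + d
  }
  bits + (k + (n - k) %% d) * log2A
}

# All sequences of a given length over {0, .., A-1}, one per row.
all_sequences <- function(len, A) {
  as.matrix(do.call(expand.grid, rep(list(0:(A - 1L)), len)))
}

# Confusion-matrix metrics by direct enumeration (fuzz oracle).
oracle_metrics <- function(truth, pred, positive) {
  n <- length(truth)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(n)) {
    if (truth[i] == positive && pred[i] == positive) tp <- tp + 1L
    if (truth[i] != positive && pred[i] == positive) fp <- fp + 1L
    if (truth[i] != positive && pred[i] != positive) tn <- tn + 1L
    if (truth[i] == positive && pred[i] != positive) fn <- fn + 1L
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(
    accuracy = (tp + tn) / n,
    recall = rec,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    precision = prec,
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  )
}

# Best equal-width L-bin quantizer MSE (oracle for Lloyd-Max optimality
# comparisons).
uniform_binning_mse <- function(x, L) {
  edges <- seq(min(x), max(x), length.out = L + 1L)
  cell <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), L)
  centers <- tapply(x, factor(cell, levels = seq_len(L)), mean)
  centers[is.na(centers)] <- 0
  mean((x - centers[cell])^2)
}

# A small fully preprocessed feature table for fold/balance tests: 7
# originals in the minority class, n_major majority rows, p iid features.
toy_feature_table <- function(n_minor = 7L, n_major = 54L, p = 4L,
                              seed = 1L) {
  set.seed(seed)
  n <- n_minor + n_major
  x <- matrix(rnorm(n * p), n, p)
  combos <- expand.grid(
    component = c("trend", "residual"), slot = letters[1:6],
    stringsAsFactors = FALSE
  )[seq_len(p), ]
  colnames(x) <- feature_name(
    rep("maternal-fetal NRC", p),
    paste0("h2-", combos$slot), combos$component
  )
  dplyr::bind_cols(
    tibble::tibble(
      case_id = sprintf("c%02d", seq_len(n)),
      group = rep(c("acidemic", "nonacidemic"), c(n_minor, n_major)),
      ph = c(runif(n_minor, 7, 7.14), runif(n_major, 7.16, 7.37)),
      origin = "original"
    ),
    tibble::as_tibble(x)
  )
}

feature_name <- function(family, label, component) {
  paste(family, label, component, sep = " — ")
}

small_cohort <- function(seed = 1L, effect_size = 1, n_non = 3L, n_acid = 3L,
                         duration_min = 50) {
  generate_cohort(cohort_config(
    n_nonacidemic = n_non, n_acidemic = n_acid,
    duration_min = duration_min, jitter_min = 1,
    effect_size = effect_size, seed = seed
  ))
}
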