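## Internal helpers shared across modules.

#' Derive a child seed from a master seed and a stage label
#'
#' Deterministic fan-out of one master seed into per-stage seeds so that
#' pipeline stages draw from independent, reproducible streams. The result
#' always fits in a 32-bit signed integer.
#'
#' @param seed master seed (single integer).
#' @param label character stage label.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 2654435761 + h * 97 + 13) %% .Machine$integer.max)
}

# Stratified fold assignment: within each outcome level, observations are
# shuffled and dealt round-robin so every fold sees every level that has at
# least `folds` cases. Returns an integer vector of fold ids in 1..folds.
stratified_folds <- function(y, folds) {
  stopifnot(folds >= 2L, length(y) >= folds)
  assign <- integer(length(y))
  offset <- 0L
  for (lev in unique(sort(y))) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- 1L + (seq_along(idx) - 1L + offset) %% folds
    offset <- offset + length(idx)
  }
  assign
}

# Validate an integer-valued matrix/vector against an inclusive range.
check_range <- function(x, lo, hi, what) {
  if (any(!is.finite(x)) || any(x != floor(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("%s must be integers in [%d, %d]", what, lo, hi), call. = FALSE)
  }
  invisible(x)
}

# Percentile bootstrap CI for a statistic of a vector (resampling rows).
boot_ci <- function(x, stat, B = 2000L, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  reps <- vapply(seq_len(B), function(b) stat(x[sample.int(n, replace = TRUE)]),
                 numeric(1))
  a <- (1 - level) / 2
  unname(stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
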