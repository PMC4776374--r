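#' Round half away from zero
#'
#' Reported ratios in family summaries use conventional "half up" rounding
#' (82.35 -> 82.4), not the IEEE banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return `x` rounded, halves moving away from zero.
#' @examples
#' round_half_away(82.35, 1)  # 82.4
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  # tiny guard: quantities here are rationals k/n whose decimal image can sit
  # a few ulp below the exact half
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' One-decimal percentage of a count
#'
#' @param k integer numerator, `0 <= k <= n`.
#' @param n positive integer denominator.
#' @return `round(100 * k / n, 1)` with halves away from zero.
#' @examples
#' percentage(340, 464)  # 73.3
#' percentage(14, 17)    # 82.4
#' @export
percentage <- function(k, n) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop("n must be a positive integer")
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  round_half_away(100 * k / n, 1)
}

#' One-decimal fold ratio
#'
#' @param a numerator count.
#' @param b positive denominator count.
#' @return `round(a / b, 1)` with halves away from zero.
#' @examples
#' fold_ratio(467, 213)  # 2.2
#' @export
fold_ratio <- function(a, b) {
  if (length(b) != 1L || is.na(b) || b <= 0) stop("b must be positive")
  round_half_away(a / b, 1)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generators funnel through this so each
# is a pure function of (config, seed).
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# write/read plain TSV with stable formatting (deterministic bytes)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
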