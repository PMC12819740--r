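# Internal helpers shared across modules.

#' Min-max normalisation with a neutral value for degenerate input
#'
#' Rescales `x` to `[0, 1]`. When all values are equal the scale is
#' undefined; every element is mapped to the neutral midpoint 0.5 so a
#' degenerate component neither rewards nor penalises any candidate.
#'
#' @param x Numeric vector.
#' @param warn_constant Emit a warning when the input is constant.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @keywords internal
minmax <- function(x, warn_constant = FALSE) {
  rng <- range(x)
  if (diff(rng) <= 0) {
    if (warn_constant) warn("constant metric: min-max scale undefined, using neutral 0.5")
    return(rep(0.5, length(x)))
  }
  (x - rng[1]) / diff(rng)
}

# Derive a child RNG seed from a root seed and a stage label, deterministically
# and within the 32-bit integer range R requires.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Gap between two half-open intervals on the same sequence: 0 iff they
# overlap, otherwise the number of bases strictly between them.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start2 - end1, start1 - end2))
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# One-sided (over-representation) hypergeometric tail:
# P[X >= k] for X ~ Hypergeom(white = K, black = N - K, drawn = n).
hyper_tail <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
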