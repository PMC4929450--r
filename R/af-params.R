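AF_METHODS <- c("d2", "cvt", "ffp", "spaced", "cophylog",
                "acs", "kmacs", "gram", "kr")

#' Parameter bundle for an alignment-free method
#'
#' Records the tuning of one of the nine AF distances: `k` (word length for
#' `d2`, `cvt`, `ffp`), `K` (half-context length for `cophylog`),
#' `n_patterns`/`pattern_length`/`pattern_weight` and `seed` (for `spaced`)
#' and `mm` (mismatches for `kmacs`). Parameters irrelevant to a method are
#' kept but ignored.
#'
#' @param method One of `r paste(AF_METHODS, collapse = ", ")`.
#' @param k Word length.
#' @param K Half-context length.
#' @param n_patterns Number of spaced patterns.
#' @param pattern_length,pattern_weight Length and number of match positions
#'   of each spaced pattern (first and last positions always match).
#' @param mm Allowed mismatches for the kmacs greedy extension.
#' @param seed Seed for spaced-pattern generation.
#' @param both_strands Count/search both the sequence and its reverse
#'   complement (default); set `FALSE` for forward-strand-only comparison.
#' @return An object of class `af_params`.
#' @export
#' @examples
#' af_params("cophylog", K = 8)
af_params <- function(method, k = 8L, K = 8L, n_patterns = 40L,
                      pattern_length = 14L, pattern_weight = 8L,
                      mm = 4L, seed = 1L, both_strands = TRUE) {
  method <- match.arg(method, AF_METHODS)
  p <- list(method = method, k = as.integer(k), K = as.integer(K),
            n_patterns = as.integer(n_patterns),
            pattern_length = as.integer(pattern_length),
            pattern_weight = as.integer(pattern_weight),
            mm = as.integer(mm), seed = as.integer(seed),
            both_strands = isTRUE(both_strands))
  stopifnot(p$k >= 1, p$K >= 1, p$n_patterns >= 1, p$mm >= 0,
            p$pattern_weight >= 2, p$pattern_length >= p$pattern_weight)
  class(p) <- "af_params"
  p
}

#' @export
print.af_params <- function(x, ...) {
  key <- switch(x$method,
    d2 = , cvt = , ffp = paste0("k=", x$k),
    cophylog = paste0("K=", x$K),
    spaced = paste0("n=", x$n_patterns, " (", x$pattern_length, "/",
                    x$pattern_weight, ")"),
    kmacs = paste0("mm=", x$mm),
    "defaults")
  cat("af_params:", x$method, key,
      if (!x$both_strands) "[forward only]" else "", "\n")
  invisible(x)
}

#' Generate binary spaced-word patterns
#'
#' Patterns are strings of `1` (match) and `0` (don't care) of fixed length
#' and weight; the first and last positions are always match positions. The
#' generator is deterministic given the seed and rejects duplicates.
#'
#' @param n Number of patterns.
#' @param length Pattern length.
#' @param weight Number of match positions.
#' @param seed Integer seed.
#' @return Character vector of `n` distinct patterns.
#' @export
#' @examples
#' generate_spaced_patterns(3, 8, 4, seed = 1)
generate_spaced_patterns <- function(n, length = 14L, weight = 8L,
                                     seed = 1L) {
  L <- as.integer(length)
  rm(length)  # unshadow base::length
  stopifnot(weight >= 2, L >= weight)
  n_inner <- choose(L - 2L, weight - 2L)
  if (n > n_inner)
    stop("only ", n_inner, " distinct patterns of length ", L,
         " and weight ", weight, " exist")
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    v <- rep("0", L)
    v[c(1L, L)] <- "1"
    if (weight > 2L)
      v[sample(2:(L - 1L), weight - 2L)] <- "1"
    p <- paste(v, collapse = "")
    if (!p %in% out) out <- c(out, p)
  }
  out
}
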