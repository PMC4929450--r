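# The nine alignment-free distances. Word-count methods (d2, cvt, ffp,
# spaced, co-phylog) work on k-mer/spaced-word/context statistics; the
# match-length methods (acs, kmacs, gram, kr) on common-substring lengths.
# By default every method treats genomes as double-stranded: word counts
# pool the sequence and its reverse complement, match searches look in the
# target and its reverse complement.

merge_profiles <- function(px, py) {
  codes <- sort(unique(c(px$codes, py$codes)))
  fx <- numeric(length(codes)); fy <- numeric(length(codes))
  fx[match(px$codes, codes)] <- px$counts
  fy[match(py$codes, codes)] <- py$counts
  list(codes = codes, x = fx, y = fy)
}

#' Word-count cosine distance (D2)
#'
#' `D2 = sum_w c_x(w) c_y(w)` over all `k`-words; the distance is the cosine
#' form `1 - D2 / sqrt(sum c_x^2 * sum c_y^2)`.
#'
#' @param x,y Nucleotide sequences (single character strings).
#' @param k Word length.
#' @param both_strands Count both strands (default `TRUE`).
#' @return Distance in `[0, 2]` (0 for identical count vectors).
#' @export
#' @examples
#' d2_distance("ACGT", "ACGA", k = 2, both_strands = FALSE)  # 1/3
d2_distance <- function(x, y, k, both_strands = TRUE) {
  check_seq(x, "x", k); check_seq(y, "y", k)
  px <- cpp_kmer_counts(x, k, both_strands)
  py <- cpp_kmer_counts(y, k, both_strands)
  j <- match(px$codes, py$codes)
  dot <- sum(px$counts * py$counts[j], na.rm = TRUE)
  den <- sqrt(sum(px$counts^2) * sum(py$counts^2))
  if (den == 0) return(0)
  1 - dot / den
}

#' Feature frequency profile distance (Jensen-Shannon divergence)
#'
#' Jensen-Shannon divergence (log base 2, hence in `[0, 1]`) between the
#' normalized `k`-mer frequency profiles of the two sequences.
#'
#' @inheritParams d2_distance
#' @return Distance in `[0, 1]`.
#' @export
ffp_distance <- function(x, y, k, both_strands = TRUE) {
  check_seq(x, "x", k); check_seq(y, "y", k)
  pr <- merge_profiles(cpp_kmer_counts(x, k, both_strands),
                       cpp_kmer_counts(y, k, both_strands))
  p <- pr$x / sum(pr$x)
  q <- pr$y / sum(pr$y)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# composition-vector components a(w) = (p(w) - p0(w)) / p0(w) with the
# Markov-order k-2 expectation p0(w) = p(prefix) p(suffix) / p(middle);
# exact dense vector over all 4^k words for k <= 10
cvt_vector_dense <- function(s, k, both_strands) {
  nk <- 4^k
  fill <- function(kk) {
    pr <- cpp_kmer_counts(s, kk, both_strands)
    v <- numeric(4^kk)
    v[pr$codes + 1] <- pr$counts
    v / sum(v)
  }
  p <- fill(k); p1 <- fill(k - 1L); p2 <- fill(k - 2L)
  idx <- 0:(nk - 1)
  pre <- idx %/% 4
  suf <- idx %% (4^(k - 1))
  mid <- suf %/% 4
  p0 <- p1[pre + 1] * p1[suf + 1]
  pm <- p2[mid + 1]
  p0 <- ifelse(pm > 0, p0 / pm, 0)
  ifelse(p0 > 0, (p - p0) / p0, 0)
}

# sparse variant for large k: components restricted to words observed in at
# least one of the two sequences (the dense a(w) = -1 tail is dropped)
cvt_components_sparse <- function(sx, sy, k, both_strands) {
  prof <- function(s, kk) cpp_kmer_counts(s, kk, both_strands)
  ax <- prof(sx, k); ay <- prof(sy, k)
  codes <- sort(unique(c(ax$codes, ay$codes)))
  comp <- function(pk, p1, p2, codes) {
    tot <- sum(pk$counts)
    p <- numeric(length(codes))
    p[match(pk$codes, codes)] <- pk$counts / tot
    look <- function(pr, cd) {
      v <- pr$counts[match(cd, pr$codes)] / sum(pr$counts)
      v[is.na(v)] <- 0
      v
    }
    pre <- codes %/% 4
    suf <- codes %% (4^(k - 1))
    mid <- suf %/% 4
    p0 <- look(p1, pre) * look(p1, suf)
    pm <- look(p2, mid)
    p0 <- ifelse(pm > 0, p0 / pm, 0)
    ifelse(p0 > 0, (p - p0) / p0, 0)
  }
  x1 <- prof(sx, k - 1L); x2 <- prof(sx, k - 2L)
  y1 <- prof(sy, k - 1L); y2 <- prof(sy, k - 2L)
  list(x = comp(ax, x1, x2, codes), y = comp(ay, y1, y2, codes))
}

cvt_cosine_distance <- function(vx, vy) {
  den <- sqrt(sum(vx^2) * sum(vy^2))
  cosv <- if (den > 0) sum(vx * vy) / den else 0
  (1 - cosv) / 2
}

#' Composition vector distance
#'
#' Composition-vector components subtract a Markov-order `k - 2` background
#' expectation from each word frequency; the distance is
#' `(1 - cosine) / 2` between the two component vectors, in `[0, 1]`.
#' For `k <= 10` the vectors are dense over all `4^k` words (exact); above
#' that they are restricted to the words observed in either sequence.
#'
#' @inheritParams d2_distance
#' @return Distance in `[0, 1]`.
#' @export
cvt_distance <- function(x, y, k, both_strands = TRUE) {
  if (k < 3) stop("cvt requires k >= 3 (Markov expectation undefined)")
  check_seq(x, "x", k); check_seq(y, "y", k)
  if (k <= 10) {
    cvt_cosine_distance(cvt_vector_dense(x, k, both_strands),
                        cvt_vector_dense(y, k, both_strands))
  } else {
    v <- cvt_components_sparse(x, y, k, both_strands)
    cvt_cosine_distance(v$x, v$y)
  }
}

#' Spaced-words distance
#'
#' For each binary pattern, spaced words are read off the match positions of
#' every window; the distance is the mean over patterns of the Euclidean
#' distance between the frequency-normalized spaced-word vectors.
#'
#' @inheritParams d2_distance
#' @param params An [af_params()] with method `"spaced"` (supplies the
#'   pattern count, length, weight and generation seed), or a character
#'   vector of explicit patterns.
#' @return Non-negative distance (0 for identical sequences).
#' @export
spaced_distance <- function(x, y, params, both_strands = NULL) {
  if (is.null(both_strands))
    both_strands <- if (inherits(params, "af_params")) params$both_strands
                    else TRUE
  pats <- if (is.character(params)) params
          else generate_spaced_patterns(params$n_patterns,
                                        params$pattern_length,
                                        params$pattern_weight, params$seed)
  check_seq(x, "x", nchar(pats[1])); check_seq(y, "y", nchar(pats[1]))
  d <- vapply(pats, function(p) {
    pr <- merge_profiles(cpp_spaced_counts(x, p, both_strands),
                         cpp_spaced_counts(y, p, both_strands))
    sqrt(sum((pr$x / sum(pr$x) - pr$y / sum(pr$y))^2))
  }, 0)
  mean(d)
}

#' Co-phylog context-object distance
#'
#' Every position contributes a context (the `K` nt on each side) and an
#' object (the middle nt). Contexts mapping to more than one object within a
#' genome are discarded; the distance is the fraction of contexts shared by
#' the two genomes whose objects differ.
#'
#' @inheritParams d2_distance
#' @param K Half-context length.
#' @return Distance in `[0, 1]`.
#' @export
cophylog_distance <- function(x, y, K, both_strands = TRUE) {
  check_seq(x, "x", 2 * K + 1); check_seq(y, "y", 2 * K + 1)
  ct <- cpp_cophylog_counts(x, y, K, both_strands)
  if (ct[1] == 0)
    stop("co-phylog distance undefined: no shared contexts between the ",
         "two sequences at K = ", K)
  ct[2] / ct[1]
}

# average common substring machinery shared by acs and kmacs
acs_score <- function(lx_in_y, ly_in_x, nx, ny) {
  Lxy <- mean(lx_in_y)
  Lyx <- mean(ly_in_x)
  if (Lxy == 0 || Lyx == 0) return(Inf)
  dxy <- log(ny) / Lxy - 2 * log(nx) / nx
  dyx <- log(nx) / Lyx - 2 * log(ny) / ny
  max(0, (dxy + dyx) / 2)
}

#' Average common substring distance
#'
#' For each position of `x`, the length of the longest prefix of the suffix
#' starting there that occurs anywhere in `y` (and vice versa); the mean
#' lengths enter the ACS score `log|y|/L(x,y) - 2 log|x|/|x|`, symmetrized
#' and floored at 0.
#'
#' @inheritParams d2_distance
#' @return Non-negative distance (0 for identical sequences).
#' @export
acs_distance <- function(x, y, both_strands = TRUE) {
  check_seq(x, "x", 2); check_seq(y, "y", 2)
  acs_score(cpp_match_lengths(x, y, both_strands),
            cpp_match_lengths(y, x, both_strands),
            nchar(x), nchar(y))
}

#' kmacs distance (average common substrings with mismatches)
#'
#' As [acs_distance()], but each match length is extended greedily across up
#' to `mm` mismatch positions: starting from the leftmost occurrence in the
#' target of the longest exact match, a mismatch is consumed and exact
#' matching resumes, up to `mm` times. `mm = 0` reduces exactly to ACS.
#'
#' @inheritParams d2_distance
#' @param mm Number of allowed mismatches.
#' @return Non-negative distance.
#' @export
kmacs_distance <- function(x, y, mm, both_strands = TRUE) {
  check_seq(x, "x", 2); check_seq(y, "y", 2)
  acs_score(cpp_kmacs_lengths(x, y, mm, both_strands),
            cpp_kmacs_lengths(y, x, mm, both_strands),
            nchar(x), nchar(y))
}

#' Lempel-Ziv cross-complexity distance
#'
#' With `c(s)` the LZ76 phrase count of `s` and `c(x|y) = c(concat(y, x)) -
#' c(y)` the additional phrases needed for `x` after seeing `y`, the
#' distance is `(c(x|y) + c(y|x)) / (c(x) + c(y))`. With
#' `both_strands = TRUE` the conditioning side is augmented with its reverse
#' complement.
#'
#' @inheritParams d2_distance
#' @return Non-negative distance, symmetric by construction.
#' @export
gram_distance <- function(x, y, both_strands = TRUE) {
  check_seq(x, "x"); check_seq(y, "y")
  x_aug <- if (both_strands) paste0(x, cpp_revcomp(x)) else x
  y_aug <- if (both_strands) paste0(y, cpp_revcomp(y)) else y
  cx <- cpp_lz_phrases(x)
  cy <- cpp_lz_phrases(y)
  cxy <- cpp_lz_phrases(paste0(y_aug, x)) - cpp_lz_phrases(y_aug)
  cyx <- cpp_lz_phrases(paste0(x_aug, y)) - cpp_lz_phrases(x_aug)
  (cxy + cyx) / (cx + cy)
}

# expected shortest-absent-prefix length for mismatch fraction pi against a
# target of effective length m: shulen = 1 + sum_l P(max(background match,
# homologous run) >= l), background P = 1 - (1 - 4^-l)^m
expected_shulen <- function(pi, m) {
  lmax <- 300L
  l <- seq_len(lmax)
  pG <- -expm1(m * log1p(-(0.25^l)))
  sG <- sum(pG)
  sH <- (1 - pi) / pi
  sGH <- sum(pG * (1 - pi)^l)
  1 + sG + sH - sGH
}

#' Kr distance (shortest unique substrings with Jukes-Cantor correction)
#'
#' For each position of `x`, the shulen is the length of the shortest
#' prefix of the suffix starting there that is absent from `y` (both strands
#' by default). The mean shulen is inverted against its expectation under a
#' uniform-background model with homologous mismatch fraction `pi` to give
#' `pi_hat`, then transformed with the Jukes-Cantor formula
#' `-3/4 log(1 - 4 pi_hat / 3)`.
#'
#' @inheritParams d2_distance
#' @return Non-negative distance; errors when `pi_hat >= 3/4` (saturated).
#' @export
kr_distance <- function(x, y, both_strands = TRUE) {
  check_seq(x, "x", 2); check_seq(y, "y", 2)
  est <- function(a, b) {
    sbar <- mean(cpp_shulens(a, b, both_strands))
    # whole-suffix matches are length-capped; at the cap `a` is contained
    # in `b` and the homologous mismatch fraction is zero
    if (sbar >= (nchar(a) + 1) / 2 - 1e-9) return(0)
    m_eff <- nchar(b) * if (both_strands) 2 else 1
    f <- function(p) expected_shulen(p, m_eff) - sbar
    if (f(1 - 1e-9) > 0) return(1)     # below random expectation: saturated
    if (f(1e-12) < 0) return(0)        # effectively identical
    uniroot(f, c(1e-12, 1 - 1e-9), tol = 1e-12)$root
  }
  pi_hat <- (est(x, y) + est(y, x)) / 2
  if (pi_hat >= 0.75)
    stop("kr distance saturated: estimated mismatch fraction ",
         signif(pi_hat, 3), " >= 3/4")
  max(0, -0.75 * log(1 - 4 * pi_hat / 3))
}

#' Fraction of shared k-mers (Jaccard index on distinct k-mer sets)
#'
#' @inheritParams d2_distance
#' @return `|S_x intersect S_y| / |S_x union S_y|` over distinct `k`-mers.
#' @export
#' @examples
#' shared_kmer_fraction("ACGTA", "CGTAC", k = 2, both_strands = FALSE)
shared_kmer_fraction <- function(x, y, k, both_strands = TRUE) {
  check_seq(x, "x", k); check_seq(y, "y", k)
  sx <- cpp_kmer_counts(x, k, both_strands)$codes
  sy <- cpp_kmer_counts(y, k, both_strands)$codes
  length(intersect(sx, sy)) / length(union(sx, sy))
}
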