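# Distance-matrix assembly. Word-count methods precompute one profile per
# genome; match-length methods run pairwise.

af_pair_fun <- function(params) {
  switch(params$method,
    d2 = function(x, y) d2_distance(x, y, params$k, params$both_strands),
    cvt = function(x, y) cvt_distance(x, y, params$k, params$both_strands),
    ffp = function(x, y) ffp_distance(x, y, params$k, params$both_strands),
    spaced = function(x, y) spaced_distance(x, y, params),
    cophylog = function(x, y)
      cophylog_distance(x, y, params$K, params$both_strands),
    acs = function(x, y) acs_distance(x, y, params$both_strands),
    kmacs = function(x, y)
      kmacs_distance(x, y, params$mm, params$both_strands),
    gram = function(x, y) gram_distance(x, y, params$both_strands),
    kr = function(x, y) kr_distance(x, y, params$both_strands))
}

# profile-based fast paths (equal results to the pairwise functions)
af_profile_funs <- function(params) {
  bs <- params$both_strands
  switch(params$method,
    d2 = list(
      prep = function(s) cpp_kmer_counts(s, params$k, bs),
      pair = function(px, py) {
        j <- match(px$codes, py$codes)
        dot <- sum(px$counts * py$counts[j], na.rm = TRUE)
        den <- sqrt(sum(px$counts^2) * sum(py$counts^2))
        if (den == 0) 0 else 1 - dot / den
      }),
    ffp = list(
      prep = function(s) cpp_kmer_counts(s, params$k, bs),
      pair = function(px, py) {
        pr <- merge_profiles(px, py)
        p <- pr$x / sum(pr$x); q <- pr$y / sum(pr$y)
        m <- (p + q) / 2
        kl <- function(a, b) { i <- a > 0; sum(a[i] * log2(a[i] / b[i])) }
        (kl(p, m) + kl(q, m)) / 2
      }),
    cvt = if (params$k <= 10) list(
      prep = function(s) cvt_vector_dense(s, params$k, bs),
      pair = cvt_cosine_distance) else NULL,
    spaced = list(
      prep = local({
        pats <- generate_spaced_patterns(params$n_patterns,
                                         params$pattern_length,
                                         params$pattern_weight, params$seed)
        function(s) lapply(pats, function(p) cpp_spaced_counts(s, p, bs))
      }),
      pair = function(px, py) {
        mean(mapply(function(a, b) {
          pr <- merge_profiles(a, b)
          sqrt(sum((pr$x / sum(pr$x) - pr$y / sum(pr$y))^2))
        }, px, py))
      }),
    NULL)
}

# whole-matrix fast paths (numerically identical to the pairwise calls)
af_matrix_fun <- function(params) {
  bs <- params$both_strands
  if (params$method == "cophylog") {
    return(function(seqs) {
      m <- cpp_cophylog_matrix(unname(seqs), params$K, bs)
      if (anyNA(m)) {
        bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
        stop("co-phylog distance undefined (no shared contexts) for ",
             nrow(bad), " pair(s), e.g. (", names(seqs)[bad[1, 1]], ", ",
             names(seqs)[bad[1, 2]], ") at K = ", params$K)
      }
      m
    })
  }
  if (params$method == "spaced" && params$pattern_weight <= 10) {
    return(function(seqs) {
      pats <- generate_spaced_patterns(params$n_patterns,
                                       params$pattern_length,
                                       params$pattern_weight, params$seed)
      n <- length(seqs)
      nk <- 4^params$pattern_weight
      acc <- matrix(0, n, n)
      for (p in pats) {
        f <- matrix(0, n, nk)
        for (i in seq_len(n)) {
          pr <- cpp_spaced_counts(seqs[[i]], p, bs)
          f[i, pr$codes + 1] <- pr$counts / sum(pr$counts)
        }
        acc <- acc + as.matrix(stats::dist(f))
      }
      acc / length(pats)
    })
  }
  NULL
}

as_genome_seqs <- function(genomes) {
  if (inherits(genomes, "genome_set")) return(genome_strings(genomes))
  if (inherits(genomes, "DNAbin")) return(dnabin_to_string(genomes))
  if (is.list(genomes)) genomes <- unlist(genomes)
  stopifnot(is.character(genomes))
  if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("genomes must carry unique taxon names")
  genomes
}

#' Pairwise alignment-free distance matrix
#'
#' Applies the selected AF distance to every genome pair, returning a
#' symmetric matrix with zero diagonal and taxon labels.
#'
#' @param genomes Named character vector of genome sequences, a
#'   `genome_set` from [evolve()], or a `DNAbin` list.
#' @param params An [af_params()] object selecting the method and tuning.
#' @return Symmetric numeric matrix with taxon dimnames and attribute
#'   `method`.
#' @seealso [neighbor_joining()], [write_phylip()]
#' @export
#' @examples
#' seqs <- c(a = "ACGTACGTACGTAAAT", b = "ACGTACGAACGTAAAT",
#'           c = "TTTTACGCACGCGGGC")
#' distance_matrix(seqs, af_params("d2", k = 3))
distance_matrix <- function(genomes, params) {
  seqs <- as_genome_seqs(genomes)
  n <- length(seqs)
  if (n < 3) stop("need at least 3 genomes")
  labels <- names(seqs)
  mf <- af_matrix_fun(params)
  if (!is.null(mf)) {
    m <- mf(seqs)
    dimnames(m) <- list(labels, labels)
    attr(m, "method") <- params$method
    return(m)
  }
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  pf <- af_profile_funs(params)
  if (!is.null(pf)) {
    prof <- lapply(seqs, pf$prep)
    pair <- function(i, j) pf$pair(prof[[i]], prof[[j]])
  } else {
    fn <- af_pair_fun(params)
    pair <- function(i, j) fn(seqs[[i]], seqs[[j]])
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- tryCatch(pair(i, j), error = function(e)
        stop("distance failed for pair (", labels[i], ", ", labels[j],
             "): ", conditionMessage(e), call. = FALSE))
      m[i, j] <- m[j, i] <- d
    }
  }
  attr(m, "method") <- params$method
  m
}

#' Write / read a PHYLIP square distance matrix
#'
#' Taxon names are truncated to 10 characters and space-padded, as consumed
#' by classical distance/NJ tools.
#'
#' @param m Symmetric distance matrix with taxon dimnames.
#' @param path Output file.
#' @return `path` invisibly; [read_phylip()] returns the matrix.
#' @export
write_phylip <- function(m, path) {
  labels <- rownames(m)
  short <- substr(labels, 1, 10)
  if (anyDuplicated(short))
    stop("taxon names collide after truncation to 10 characters")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(formatC(short[i], width = -10),
                      paste(sprintf("%.9f", m[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labels <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    labels[i] <- trimws(substr(lines[i + 1], 1, 10))
    m[i, ] <- as.numeric(strsplit(trimws(substr(lines[i + 1], 11,
                                                nchar(lines[i + 1]))),
                                  "\\s+")[[1]])
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' Long-format (TSV-ready) view of a distance matrix
#'
#' @param m Symmetric distance matrix with dimnames.
#' @return Data frame with columns `taxon1`, `taxon2`, `distance`, one row
#'   per unordered pair.
#' @export
distance_long <- function(m) {
  idx <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(taxon1 = rownames(m)[idx[, 1]],
             taxon2 = colnames(m)[idx[, 2]],
             distance = m[idx], stringsAsFactors = FALSE)
}
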