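# Independent brute-force oracles for the AF distances. These share only
# the published formulas with the package; every counting / matching step
# is re-derived from substring enumeration.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# named count table of all k-words (windows with non-ACGT skipped)
oracle_kmer_table <- function(s, k, both_strands) {
  words <- function(z) {
    n <- nchar(z)
    if (n < k) return(character(0))
    w <- substring(z, 1:(n - k + 1), k:n)
    w[!grepl("[^ACGT]", w)]
  }
  w <- words(s)
  if (both_strands) w <- c(w, words(oracle_revcomp(s)))
  table(w)
}

oracle_d2 <- function(x, y, k, both_strands) {
  cx <- oracle_kmer_table(x, k, both_strands)
  cy <- oracle_kmer_table(y, k, both_strands)
  shared <- intersect(names(cx), names(cy))
  d2 <- sum(as.numeric(cx[shared]) * as.numeric(cy[shared]))
  1 - d2 / sqrt(sum(as.numeric(cx)^2) * sum(as.numeric(cy)^2))
}

oracle_ffp <- function(x, y, k, both_strands) {
  cx <- oracle_kmer_table(x, k, both_strands)
  cy <- oracle_kmer_table(y, k, both_strands)
  words <- union(names(cx), names(cy))
  p <- as.numeric(cx[words]); p[is.na(p)] <- 0; p <- p / sum(p)
  q <- as.numeric(cy[words]); q[is.na(q)] <- 0; q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  (kl(p, m) + kl(q, m)) / 2
}

# composition vector over every word of length k (dense, direct summation)
oracle_cvt_vector <- function(s, k, both_strands) {
  all_words <- function(kk) {
    g <- expand.grid(rep(list(c("A", "C", "G", "T")), kk),
                     stringsAsFactors = FALSE)
    apply(g[, rev(seq_len(kk)), drop = FALSE], 1, paste, collapse = "")
  }
  freq <- function(kk) {
    tb <- oracle_kmer_table(s, kk, both_strands)
    w <- all_words(kk)
    v <- as.numeric(tb[w]); v[is.na(v)] <- 0
    names(v) <- w
    v / sum(v)
  }
  p <- freq(k); p1 <- freq(k - 1); p2 <- freq(k - 2)
  w <- names(p)
  pre <- substr(w, 1, k - 1); suf <- substr(w, 2, k)
  mid <- substr(w, 2, k - 1)
  p0 <- ifelse(p2[mid] > 0, p1[pre] * p1[suf] / p2[mid], 0)
  unname(ifelse(p0 > 0, (p - p0) / p0, 0))
}

oracle_cvt <- function(x, y, k, both_strands) {
  vx <- oracle_cvt_vector(x, k, both_strands)
  vy <- oracle_cvt_vector(y, k, both_strands)
  den <- sqrt(sum(vx^2) * sum(vy^2))
  (1 - if (den > 0) sum(vx * vy) / den else 0) / 2
}

oracle_spaced_words <- function(s, pattern, both_strands) {
  pos <- which(strsplit(pattern, "")[[1]] == "1")
  extract <- function(z) {
    n <- nchar(z); L <- nchar(pattern)
    if (n < L) return(character(0))
    out <- vapply(1:(n - L + 1), function(i) {
      ch <- substring(z, i + pos - 1, i + pos - 1)
      if (any(grepl("[^ACGT]", ch))) "" else paste(ch, collapse = "")
    }, "")
    out[out != ""]
  }
  w <- extract(s)
  if (both_strands) w <- c(w, extract(oracle_revcomp(s)))
  table(w)
}

oracle_spaced <- function(x, y, patterns, both_strands) {
  mean(vapply(patterns, function(p) {
    cx <- oracle_spaced_words(x, p, both_strands)
    cy <- oracle_spaced_words(y, p, both_strands)
    words <- union(names(cx), names(cy))
    fx <- as.numeric(cx[words]); fx[is.na(fx)] <- 0; fx <- fx / sum(fx)
    fy <- as.numeric(cy[words]); fy[is.na(fy)] <- 0; fy <- fy / sum(fy)
    sqrt(sum((fx - fy)^2))
  }, 0))
}

# context -> object maps via plain environments
oracle_cophylog_map <- function(s, K, both_strands) {
  m <- new.env(hash = TRUE)
  feed <- function(z) {
    n <- nchar(z); w <- 2 * K + 1
    if (n < w) return()
    for (i in 1:(n - w + 1)) {
      win <- substr(z, i, i + w - 1)
      if (grepl("[^ACGT]", win)) next
      ctx <- paste0(substr(win, 1, K), substr(win, K + 2, w))
      obj <- substr(win, K + 1, K + 1)
      old <- m[[ctx]]
      if (is.null(old)) m[[ctx]] <- obj
      else if (!identical(old, obj)) m[[ctx]] <- "conflict"
    }
  }
  feed(s)
  if (both_strands) feed(oracle_revcomp(s))
  m
}

oracle_cophylog <- function(x, y, K, both_strands) {
  mx <- oracle_cophylog_map(x, K, both_strands)
  my <- oracle_cophylog_map(y, K, both_strands)
  shared <- 0; diff <- 0
  for (ctx in ls(mx)) {
    ox <- mx[[ctx]]; oy <- my[[ctx]]
    if (is.null(oy) || identical(ox, "conflict") ||
        identical(oy, "conflict")) next
    shared <- shared + 1
    if (!identical(ox, oy)) diff <- diff + 1
  }
  if (shared == 0) stop("no shared contexts")
  diff / shared
}

# all (overlapping) occurrence start positions of `sub` in `y`
oracle_occurrences <- function(sub, y) {
  n <- nchar(y); l <- nchar(sub)
  if (l > n) return(integer(0))
  starts <- 1:(n - l + 1)
  starts[substring(y, starts, starts + l - 1) == sub]
}

# quadratic per-start longest-match lengths; optionally the start of the
# rightmost occurrence in y of each longest match
oracle_match_lengths <- function(x, y, with_occ = FALSE) {
  n <- nchar(x)
  ml <- integer(n); occ <- rep(-1L, n)
  for (i in 1:n) {
    l <- 0L
    while (i + l <= n) {
      sub <- substr(x, i, i + l)
      if (grepl("[^ACGT]", sub)) break
      hits <- oracle_occurrences(sub, y)
      if (length(hits) == 0) break
      l <- l + 1L
      occ[i] <- max(hits)
    }
    ml[i] <- l
  }
  if (with_occ) list(ml = ml, occ = occ) else ml
}

oracle_match_lengths_strands <- function(x, y, both_strands) {
  ml <- oracle_match_lengths(x, y)
  if (both_strands) pmax(ml, oracle_match_lengths(x, oracle_revcomp(y)))
  else ml
}

oracle_acs <- function(x, y, both_strands) {
  nx <- nchar(x); ny <- nchar(y)
  Lxy <- mean(oracle_match_lengths_strands(x, y, both_strands))
  Lyx <- mean(oracle_match_lengths_strands(y, x, both_strands))
  dxy <- log(ny) / Lxy - 2 * log(nx) / nx
  dyx <- log(nx) / Lyx - 2 * log(ny) / ny
  max(0, (dxy + dyx) / 2)
}

# greedy mismatch extension from the rightmost occurrence of the longest
# exact match (the package's documented kmacs definition)
oracle_kmacs_lengths_one <- function(x, y, mm) {
  n <- nchar(x); m <- nchar(y)
  r <- oracle_match_lengths(x, y, with_occ = TRUE)
  out <- r$ml
  if (mm == 0) return(out)
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  for (i in 1:n) {
    l <- r$ml[i]
    if (l == 0) next
    s0 <- r$occ[i]
    total <- l; used <- 0; xi <- i + l; yi <- s0 + l
    while (used < mm && xi <= n && yi <= m) {
      if (grepl("[^ACGT]", xs[xi]) || grepl("[^ACGT]", ys[yi])) break
      used <- used + 1; total <- total + 1; xi <- xi + 1; yi <- yi + 1
      while (xi <= n && yi <= m && xs[xi] == ys[yi] &&
             !grepl("[^ACGT]", xs[xi])) {
        total <- total + 1; xi <- xi + 1; yi <- yi + 1
      }
    }
    out[i] <- total
  }
  out
}

oracle_kmacs_lengths <- function(x, y, mm, both_strands) {
  out <- oracle_kmacs_lengths_one(x, y, mm)
  if (both_strands)
    out <- pmax(out, oracle_kmacs_lengths_one(x, oracle_revcomp(y), mm))
  out
}

oracle_kmacs <- function(x, y, mm, both_strands) {
  nx <- nchar(x); ny <- nchar(y)
  Lxy <- mean(oracle_kmacs_lengths(x, y, mm, both_strands))
  Lyx <- mean(oracle_kmacs_lengths(y, x, mm, both_strands))
  dxy <- log(ny) / Lxy - 2 * log(nx) / nx
  dyx <- log(nx) / Lyx - 2 * log(ny) / ny
  max(0, (dxy + dyx) / 2)
}

oracle_shulens <- function(x, y, both_strands) {
  ml <- oracle_match_lengths_strands(x, y, both_strands)
  n <- nchar(x)
  pmin(ml + 1L, n - seq_len(n) + 1L)
}

# LZ76 exhaustive-history phrase count by direct prefix search
oracle_lz_phrases <- function(s) {
  n <- nchar(s)
  if (n == 0) return(0L)
  count <- 0L; i <- 1L
  while (i <= n) {
    l <- 0L
    while (i + l <= n) {
      sub <- substr(s, i, i + l)
      hits <- gregexpr(sub, substr(s, 1, i + l), fixed = TRUE)[[1]]
      if (hits[1] == -1 || min(hits) >= i) break
      l <- l + 1L
    }
    count <- count + 1L
    i <- i + min(l + 1L, n - i + 1L)
  }
  count
}

oracle_gram <- function(x, y, both_strands) {
  x_aug <- if (both_strands) paste0(x, oracle_revcomp(x)) else x
  y_aug <- if (both_strands) paste0(y, oracle_revcomp(y)) else y
  cx <- oracle_lz_phrases(x)
  cy <- oracle_lz_phrases(y)
  cxy <- oracle_lz_phrases(paste0(y_aug, x)) - oracle_lz_phrases(y_aug)
  cyx <- oracle_lz_phrases(paste0(x_aug, y)) - oracle_lz_phrases(x_aug)
  (cxy + cyx) / (cx + cy)
}

# kr re-derived from the documented model: mean shulen matched to
# 1 + sum_l [1 - (1 - P(bg >= l)) (1 - P(hom >= l))], then Jukes-Cantor
oracle_kr <- function(x, y, both_strands) {
  one <- function(a, b) {
    sl <- oracle_shulens(a, b, both_strands)
    sbar <- mean(sl)
    if (sbar >= (nchar(a) + 1) / 2 - 1e-9) return(0)
    m <- nchar(b) * if (both_strands) 2 else 1
    ef <- function(pi) {
      l <- 1:300
      pG <- 1 - (1 - 0.25^l)^m
      1 + sum(pG) + (1 - pi) / pi - sum(pG * (1 - pi)^l) - sbar
    }
    if (ef(1 - 1e-9) > 0) return(1)
    if (ef(1e-12) < 0) return(0)
    uniroot(ef, c(1e-12, 1 - 1e-9), tol = 1e-12)$root
  }
  pi_hat <- (one(x, y) + one(y, x)) / 2
  if (pi_hat >= 0.75) stop("saturated")
  max(0, -0.75 * log(1 - 4 * pi_hat / 3))
}

oracle_shared_fraction <- function(x, y, k, both_strands) {
  sx <- names(oracle_kmer_table(x, k, both_strands))
  sy <- names(oracle_kmer_table(y, k, both_strands))
  length(intersect(sx, sy)) / length(union(sx, sy))
}

# star-phylogeny toy genomes: independent mutations of one root sequence
sim_seqs <- function(n = 5, len = 400, rate = 0.1, seed = 1) {
  set.seed(seed)
  root <- rand_seq(len)
  out <- vapply(seq_len(n), function(i) mutate_seq(root, rate), "")
  names(out) <- paste0("g", seq_len(n))
  out
}

# random point substitutions at a given per-site rate
mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- runif(length(v)) < rate
  v[hit] <- vapply(v[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(v, collapse = "")
}
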