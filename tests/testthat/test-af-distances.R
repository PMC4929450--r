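test_that("worked toy examples give their hand-computed values", {
  # orthogonal and partially shared word vectors (forward strand)
  expect_equal(d2_distance("AAAA", "CCCC", k = 2, both_strands = FALSE), 1)
  expect_equal(d2_distance("ACGT", "ACGA", k = 2, both_strands = FALSE),
               1 / 3)
  # k = 1 toy JSD: p = {A:1}, q = {A:1/2, C:1/2}
  hand <- 0.5 * log2(4 / 3) + 0.25 * log2(2 / 3) + 0.25
  expect_equal(ffp_distance("AA", "AC", k = 1, both_strands = FALSE), hand)
  # disjoint k-mer supports maximize the JSD
  expect_equal(ffp_distance("AAAA", "CCCC", k = 2, both_strands = FALSE), 1)
  expect_equal(shared_kmer_fraction("ACGTA", "CGTAC", k = 2,
                                    both_strands = FALSE), 1)
  expect_equal(shared_kmer_fraction("AAAA", "CCCC", k = 2), 0)
  expect_error(cvt_distance("ACGTACGT", "ACGTACGT", k = 2), "k >= 3")
  expect_error(d2_distance("AC", "ACGT", k = 3), "at least")
})

test_that("identity, symmetry and non-negativity hold for all methods", {
  set.seed(7)
  x <- rand_seq(300); y <- mutate_seq(x, 0.25)
  pats <- generate_spaced_patterns(4, 10, 5, seed = 2)
  fns <- list(
    d2 = function(a, b) d2_distance(a, b, 6),
    cvt = function(a, b) cvt_distance(a, b, 5),
    ffp = function(a, b) ffp_distance(a, b, 6),
    spaced = function(a, b) spaced_distance(a, b, pats),
    cophylog = function(a, b) cophylog_distance(a, b, 3),
    acs = function(a, b) acs_distance(a, b),
    kmacs = function(a, b) kmacs_distance(a, b, 4),
    gram = function(a, b) gram_distance(a, b),
    kr = function(a, b) kr_distance(a, b))
  for (nm in names(fns)) {
    f <- fns[[nm]]
    if (nm == "gram") {
      # cross-complexity of a string with itself is small but not zero
      expect_lt(f(x, x), 0.05)
    } else {
      expect_lt(abs(f(x, x)), 1e-9, label = paste(nm, "self"))
    }
    dxy <- f(x, y)
    expect_identical(dxy, f(y, x), label = paste(nm, "symmetry"))
    expect_gte(dxy, 0)
  }
  expect_true(ffp_distance(x, y, 6) <= 1)
  expect_true(cvt_distance(x, y, 5) <= 1)
  fr <- shared_kmer_fraction(x, y, 4)
  expect_true(fr >= 0 && fr <= 1)
})

test_that("kmacs with mm = 0 reduces exactly to acs", {
  set.seed(3)
  for (i in 1:10) {
    x <- rand_seq(150); y <- mutate_seq(x, 0.2)
    expect_identical(kmacs_distance(x, y, 0), acs_distance(x, y))
  }
})

test_that("mismatch extension follows the documented greedy rule", {
  x <- "AAAATAAAA"; y <- "AAAACAAAA"
  expect_identical(as.integer(afphylo:::cpp_kmacs_lengths(x, y, 1, FALSE)),
                   oracle_kmacs_lengths(x, y, 1, FALSE))
  # a unique anchor: the extension bridges the single substitution
  expect_identical(max(afphylo:::cpp_kmacs_lengths("GGGGTCCCC", "GGGGACCCC",
                                                   1, FALSE)), 9L)
  expect_identical(max(afphylo:::cpp_match_lengths("GGGGTCCCC", "GGGGACCCC",
                                                   FALSE)), 4L)
})

test_that("co-phylog counts one mismatching object per substituted site", {
  set.seed(11)
  x <- rand_seq(400)
  # substitute one position away from the edges
  pos <- 200
  old <- substr(x, pos, pos)
  y <- x
  substr(y, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  ct <- afphylo:::cpp_cophylog_counts(x, y, 5, FALSE)
  expect_identical(ct[2], 1)
  expect_equal(cophylog_distance(x, y, 5, both_strands = FALSE),
               1 / ct[1])
})

test_that("ambiguous bases are skipped by counting and stop match extension", {
  x <- "ACGTNNACGT"
  pr <- afphylo:::cpp_kmer_counts(x, 3, FALSE)
  expect_identical(sum(pr$counts), 4)  # 2 windows per clean segment
  ml <- afphylo:::cpp_match_lengths(x, "ACGTACGT", FALSE)
  expect_identical(ml[5], 0L)
  expect_identical(ml[6], 0L)
})

test_that("LZ cross-complexity of a sequence with itself is small", {
  set.seed(21)
  for (i in 1:5) {
    x <- rand_seq(150)
    shuf <- paste(sample(strsplit(x, "")[[1]]), collapse = "")
    expect_lte(gram_distance(x, x), gram_distance(x, shuf))
    expect_lt(gram_distance(x, x), 0.5)
  }
})

test_that("kr grows monotonically with the substitution rate", {
  set.seed(5)
  x <- rand_seq(1500)
  rates <- seq(0.02, 0.3, length.out = 6)
  d <- vapply(rates, function(r)
    mean(vapply(1:3, function(i) kr_distance(x, mutate_seq(x, r)), 0)), 0)
  expect_true(all(diff(d) > 0))
  expect_gt(suppressWarnings(cor(rates, d, method = "spearman")), 0.99)
})

test_that("kr saturates with an error on signal-free sequences", {
  expect_error(kr_distance(strrep("A", 300), strrep("G", 300)), "saturated")
})

test_that("every distance responds monotonically to divergence in expectation", {
  set.seed(91)
  x <- rand_seq(800)
  rates <- c(0.02, 0.08, 0.2)
  pats <- generate_spaced_patterns(4, 10, 5, seed = 3)
  fns <- list(
    d2 = function(a, b) d2_distance(a, b, 6),
    cvt = function(a, b) cvt_distance(a, b, 5),
    ffp = function(a, b) ffp_distance(a, b, 6),
    spaced = function(a, b) spaced_distance(a, b, pats),
    cophylog = function(a, b) cophylog_distance(a, b, 6),
    acs = function(a, b) acs_distance(a, b),
    kmacs = function(a, b) kmacs_distance(a, b, 4),
    gram = function(a, b) gram_distance(a, b),
    kr = function(a, b) kr_distance(a, b))
  for (nm in names(fns)) {
    d <- vapply(rates, function(r)
      mean(vapply(1:4, function(i) fns[[nm]](x, mutate_seq(x, r)), 0)), 0)
    expect_true(all(diff(d) > 0), label = paste(nm, "monotone in divergence"))
  }
})
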