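test_that("NJ recovers topology and branch lengths from additive matrices", {
  set.seed(1)
  for (i in 1:10) {
    tr <- ape::rtree(sample(6:12, 1))
    m <- cophenetic(tr)
    out <- neighbor_joining(m)
    expect_identical(rf_raw(out, tr), 0L)
    expect_equal(cophenetic(out)[rownames(m), colnames(m)], m,
                 tolerance = 1e-8)
  }
})

test_that("three taxa resolve with the closed-form branch lengths", {
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(m)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)
})

test_that("degenerate all-zero matrices give a star tree, not a crash", {
  m <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  tr <- neighbor_joining(m)
  expect_identical(tr$Nnode, 1L)
  expect_length(bipartitions(tr), 0)
})

test_that("invalid matrices are rejected", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(m), "at least 3")
  m3 <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(m3), "NaN|Inf")
})

test_that("bipartition counts follow N - 3 on resolved trees", {
  set.seed(2)
  expect_length(bipartitions(ape::rtree(4)), 1)
  expect_length(bipartitions(ape::rtree(30)), 27)
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_length(bipartitions(star), 0)
})

test_that("RF identities: self-distance 0, disjoint resolved trees at the maximum", {
  set.seed(3)
  tr <- ape::rtree(30)
  expect_identical(rf_raw(tr, tr), 0L)
  expect_identical(rf_normalized(tr, tr), 0)

  t1 <- ape::read.tree(text = "(((((a,b),c),d),e),(f,g));")
  t2 <- ape::read.tree(text = "(((((a,g),d),b),f),(c,e));")
  expect_identical(rf_raw(t1, t2), 8L)       # no shared split, 2 * (7 - 3)
  expect_identical(rf_normalized(t1, t2), 1)

  two4 <- rf_raw(ape::read.tree(text = "((a,b),(c,d));"),
                 ape::read.tree(text = "((a,c),(b,d));"))
  expect_identical(two4, 2L)
})

test_that("a single NNI changes the RF distance by exactly 2", {
  nni_pairs <- list(
    c("((a,b),((c,d),(e,f)));", "((a,b),((c,(e,f)),d));"),
    c("(((a,b),c),(d,(e,f)));", "(((a,c),b),(d,(e,f)));"),
    c("((((a,b),c),d),(e,f));", "((((a,b),d),c),(e,f));"))
  for (p in nni_pairs) {
    expect_identical(rf_raw(ape::read.tree(text = p[1]),
                            ape::read.tree(text = p[2])), 2L)
  }
})

test_that("rf_raw agrees with an independent implementation on random pairs", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    t1 <- ape::rtree(n); t2 <- ape::rtree(n)
    t2$tip.label <- sample(t1$tip.label)
    expect_identical(rf_raw(t1, t2),
                     as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("rf_raw is a metric on resolved trees", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    trees <- lapply(1:3, function(j) {
      t <- ape::rtree(n); t$tip.label <- paste0("x", sample(n)); t
    })
    d12 <- rf_raw(trees[[1]], trees[[2]])
    d13 <- rf_raw(trees[[1]], trees[[3]])
    d23 <- rf_raw(trees[[2]], trees[[3]])
    expect_identical(d12, rf_raw(trees[[2]], trees[[1]]))
    expect_lte(d12, d13 + d23)
    expect_true(rf_normalized(trees[[1]], trees[[2]]) >= 0 &&
                rf_normalized(trees[[1]], trees[[2]]) <= 1)
  }
})

test_that("mismatched leaf sets raise an error naming the difference", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,b),(c,e));")
  expect_error(rf_raw(t1, t2), "d")
  expect_error(rf_raw(t1, t2), "e")
})

test_that("NJ is robust to perturbations within the additive safety margin", {
  set.seed(7)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    tr$edge.length <- tr$edge.length + 1  # min branch >= 1
    m <- cophenetic(tr)
    eps <- matrix(runif(64, -0.2, 0.2), 8, 8)
    eps <- (eps + t(eps)) / 2; diag(eps) <- 0
    expect_identical(rf_raw(neighbor_joining(m + eps), tr), 0L)
  }
})

test_that("Newick round-trips preserve topology, lengths and labels", {
  set.seed(8)
  for (i in 1:20) {
    tr <- ape::unroot(ape::rtree(sample(4:20, 1)))
    f <- tempfile()
    newick_write(tr, f)
    back <- newick_read(f)
    expect_identical(rf_raw(back, tr), 0L)
    expect_equal(sum(back$edge.length), sum(tr$edge.length),
                 tolerance = 1e-9)
  }
  # rooted input is unrooted on load; split count drops to N - 3
  rooted <- ape::rtree(10)
  back <- newick_read(text = ape::write.tree(rooted))
  expect_false(ape::is.rooted(back))
  expect_length(bipartitions(back), 7)
  # support labels survive verbatim
  lbl <- "((a:1,b:1)95:1,(c:1,d:1)87:1);"
  tr2 <- newick_read(text = lbl, unroot = FALSE)
  expect_true(all(c("95", "87") %in% tr2$node.label))
  expect_error(newick_read(text = "((a,b,(c;"), "")
})
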