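test_that("deletion arithmetic follows floor((L * rate) / fragment)", {
  s <- strrep("ACGT", 2500)  # L = 10000
  out <- delete_fragments(s, rate = 0.4, fragment_length = 100, seed = 1)
  expect_identical(nchar(out), 6000L)
  # floor effect: L = 10050 still deletes 40 fragments
  s2 <- paste0(s, strrep("A", 50))
  out2 <- delete_fragments(s2, rate = 0.4, fragment_length = 100, seed = 1)
  expect_identical(nchar(out2), 6050L)
  # deleted fraction within [rate - fragment/L, rate]
  frac <- 1 - nchar(out2) / nchar(s2)
  expect_true(frac <= 0.4 && frac >= 0.4 - 100 / 10050)
})

test_that("tiny rates delete nothing; fixed seeds reproduce; infeasible errors", {
  s <- rand_seq(500)
  expect_identical(delete_fragments(s, rate = 0.1, fragment_length = 100,
                                    seed = 2), s)  # n_del = 0
  a <- delete_fragments(s, rate = 0.5, fragment_length = 50, seed = 7)
  b <- delete_fragments(s, rate = 0.5, fragment_length = 50, seed = 7)
  expect_identical(a, b)
  # sequences shorter than one fragment cannot lose anything
  expect_identical(delete_fragments(strrep("A", 50), rate = 0.9,
                                    fragment_length = 100), strrep("A", 50))
})

test_that("pseudo-replicates are independent given the seed stream", {
  seqs <- setNames(vapply(1:8, function(i) rand_seq(1000), ""),
                   paste0("g", 1:8))
  reps <- pseudo_replicates(seqs, jackknife_config(replicates = 5, seed = 3))
  expect_length(reps, 5)
  expect_identical(sum(lengths(reps)), 40L)
  expect_true(all(vapply(reps, function(r) all(nchar(r) == 600), TRUE)))
  expect_false(identical(reps[[1]], reps[[2]]))
  reps2 <- pseudo_replicates(seqs, jackknife_config(replicates = 5, seed = 4))
  expect_false(identical(reps[[1]], reps2[[1]]))
})

test_that("support counts replicate trees containing each split", {
  test <- ape::read.tree(text = "((a,b),(c,d),e);")
  with_ab <- ape::read.tree(text = "((a,b),(c,e),d);")
  without <- ape::read.tree(text = "((a,c),(b,d),e);")
  out <- jackknife_support(test, list(with_ab, with_ab, with_ab, without))
  labs <- out$node.label[out$node.label != ""]
  expect_setequal(labs, c("75", "0"))  # ab in 3 of 4, cd in none
  # all-identical replicates: every split at 100
  out2 <- jackknife_support(test, list(test, test))
  expect_setequal(out2$node.label[out2$node.label != ""], "100")
  # a split absent everywhere scores 0
  out3 <- jackknife_support(test, list(without))
  expect_true("0" %in% out3$node.label)
  # replicate order is irrelevant
  out4 <- jackknife_support(test, list(without, with_ab, with_ab, with_ab))
  expect_identical(out$node.label, out4$node.label)
})

test_that("single-replicate supports are 0 or 100", {
  seqs <- sim_seqs(6, len = 2000, rate = 0.05, seed = 5)
  tr <- jackknife_pipeline(seqs, af_params("d2", k = 8),
                           jackknife_config(replicates = 1, seed = 1))
  labs <- tr$node.label[tr$node.label != ""]
  expect_true(all(labs %in% c("0", "100")))
})

test_that("identical genomes collapse to a star with no supported edges", {
  seqs <- setNames(rep(rand_seq(2000), 5), paste0("g", 1:5))
  tr <- jackknife_pipeline(seqs, af_params("d2", k = 8),
                           jackknife_config(replicates = 2, seed = 1))
  expect_length(bipartitions(tr), 0)
})

test_that("a clean deep split earns high jackknife support", {
  cfg <- sim_config(taxa_range = c(10, 10), genes_range = c(30, 35),
                    gene_length_range = c(150, 250), iterations = 300,
                    mutation_rate = 0.3, seed = 17)
  gs <- evolve(cfg)
  seqs <- genome_strings(gs)
  tr <- jackknife_pipeline(seqs, af_params("d2", k = 12),
                           jackknife_config(replicates = 20, seed = 2))
  # the true tree's longest internal edge defines the deep split
  ref <- gs$tree
  st <- afphylo:::split_table(ref)
  ntip <- length(ref$tip.label)
  elen <- setNames(ref$edge.length, ref$edge[, 2])
  deep <- st$keys[which.max(elen[as.character(st$nodes)])]
  test_splits <- afphylo:::split_table(tr)
  expect_true(deep %in% test_splits$keys)
  supp <- as.integer(tr$node.label[test_splits$nodes[test_splits$keys == deep]
                                   - length(tr$tip.label)])
  expect_gte(supp, 90)
})

test_that("true-split support approaches 100 as phylogenetic signal grows", {
  # the deletion jackknife resamples informative sites: at fixed divergence,
  # larger genomes leave less resampling noise and supports rise toward 100
  mean_support <- function(ngenes, seed) {
    cfg <- sim_config(taxa_range = c(8, 8),
                      genes_range = c(ngenes, ngenes),
                      gene_length_range = c(150, 200), iterations = 300,
                      mutation_rate = 0.5, seed = seed)
    gs <- evolve(cfg)
    tr <- jackknife_pipeline(genome_strings(gs), af_params("d2", k = 10),
                             jackknife_config(replicates = 10, seed = 1))
    shared <- intersect(bipartitions(tr), bipartitions(gs$tree))
    st <- afphylo:::split_table(tr)
    supp <- as.integer(tr$node.label[st$nodes - length(tr$tip.label)])
    mean(supp[st$keys %in% shared])
  }
  means <- vapply(c(6, 15, 40), function(g)
    mean(vapply(1:3, function(s) mean_support(g, s), 0)), 0)
  expect_true(all(diff(means) >= 0))
  expect_gte(means[3], 90)
})
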