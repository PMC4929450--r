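tiny_cfg <- function(...) {
  reduced_sim_config(taxa_range = c(6, 8), genes_range = c(25, 30),
                     gene_length_range = c(120, 180), iterations = 200, ...)
}

test_that("run_scenario bookkeeping: rows, aggregation, determinism", {
  sr <- run_scenario("lgt", grid = 5,
                     methods = list(d2_k8 = af_params("d2", k = 8)),
                     replicates = 2, config = tiny_cfg(), seed = 4)
  expect_identical(nrow(sr$results), 2L)
  expect_identical(nrow(sr$summary), 1L)
  expect_equal(sr$summary$mean_rf, mean(sr$results$rf))
  expect_equal(sr$summary$sd_rf, sd(sr$results$rf))
  sr2 <- run_scenario("lgt", grid = 5,
                      methods = list(d2_k8 = af_params("d2", k = 8)),
                      replicates = 2, config = tiny_cfg(), seed = 4)
  expect_identical(sr$results, sr2$results)
})

test_that("near-zero divergence recovers the reference tree", {
  sr <- run_scenario("divergence", grid = 0.1,
                     methods = list(d2_k10 = af_params("d2", k = 10)),
                     replicates = 3, config = tiny_cfg(), seed = 11)
  expect_lte(sr$summary$mean_rf, 0.1)
})

test_that("heavy LGT degrades accuracy relative to none", {
  sr <- run_scenario("lgt", grid = c(0, 500),
                     methods = list(cophylog_K8 = af_params("cophylog",
                                                            K = 8)),
                     replicates = 8, config = reduced_sim_config(),
                     seed = 21)
  s <- sr$summary
  expect_gte(s$mean_rf[s$grid == 500], s$mean_rf[s$grid == 0])
})

test_that("the optimal-parameter rule minimizes the grand mean with ties to smaller settings", {
  methods <- list(kmacs_mm1 = af_params("kmacs", mm = 1),
                  kmacs_mm4 = af_params("kmacs", mm = 4))
  sr <- structure(list(
    scenario = "lgt", grid = c(0, 5), methods = methods, replicates = 1,
    seed = 1,
    summary = data.frame(
      scenario = "lgt", grid = c(0, 5, 0, 5),
      method = rep(c("kmacs_mm1", "kmacs_mm4"), each = 2),
      mean_rf = c(0.10, 0.20, 0.12, 0.14), sd_rf = 0, n = 1,
      n_failed = 0)), class = "scenario_result")
  best <- select_optimal_params(sr)
  expect_identical(best$kmacs$label, "kmacs_mm4")  # 0.13 beats 0.15
  expect_equal(best$kmacs$grand_mean_rf, 0.13)
  # exact tie resolves to the smaller mm
  sr$summary$mean_rf <- c(0.10, 0.16, 0.12, 0.14)
  expect_identical(select_optimal_params(sr)$kmacs$label, "kmacs_mm1")
  # incomplete grids are refused by name
  sr$summary <- sr$summary[-2, ]
  expect_error(select_optimal_params(sr), "kmacs_mm1")
})

test_that("report writes deterministic TSVs", {
  sr <- run_scenario("rearrangement", grid = c(0, 1),
                     methods = list(d2_k8 = af_params("d2", k = 8)),
                     replicates = 2, config = tiny_cfg(), seed = 6)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- report(sr, d1)
  expect_identical(nrow(read.table(p1["results"], sep = "\t",
                                   header = TRUE)), 4L)
  sr2 <- run_scenario("rearrangement", grid = c(0, 1),
                      methods = list(d2_k8 = af_params("d2", k = 8)),
                      replicates = 2, config = tiny_cfg(), seed = 6)
  p2 <- report(sr2, d2)
  expect_identical(readLines(p1["results"]), readLines(p2["results"]))
  # empty result sets still produce a header
  sr$results <- sr$results[0, ]
  sr$summary <- sr$summary[0, ]
  p3 <- report(sr, tempfile())
  expect_identical(length(readLines(p3["results"])), 1L)
})

test_that("the LGT analog preserves per-gene transfer load", {
  cfg <- reduced_sim_config()
  # accepted transfers per gene over a full-depth run at the l = 250 analog
  l250 <- lgt_rate_analog(250, cfg)
  per_gene <- l250 * cfg$iterations * cfg$receptivity$mean /
    (mean(cfg$taxa_range) * mean(cfg$genes_range))
  expect_equal(per_gene, 1, tolerance = 1e-9)
  expect_identical(lgt_rate_analog(0, cfg), 0)
  expect_equal(divergence_factor_analog(1000, cfg), 100)
  expect_identical(divergence_factor_analog(Inf, cfg), Inf)
})

test_that("empirical mode reproduces the simulation path on the same data", {
  cfg <- tiny_cfg(seed = 31)
  gs <- evolve(cfg)
  seqs <- genome_strings(gs)
  dir <- tempfile(); dir.create(dir)
  for (nm in names(seqs)) {
    ape::write.FASTA(afphylo:::string_to_dnabin(setNames(seqs[nm], nm)),
                     file.path(dir, paste0(nm, ".fasta")))
  }
  p <- af_params("d2", k = 10)
  out <- run_empirical(dir, gs$tree, p)
  direct <- rf_normalized(neighbor_joining(distance_matrix(seqs, p)),
                          gs$tree)
  expect_identical(out$rf, direct)
  expect_identical(sort(rownames(out$matrix)), sort(names(seqs)))

  # a reference leaf missing from the FASTA input is named in the error
  ref2 <- gs$tree
  ref2$tip.label[1] <- "ghost"
  expect_error(run_empirical(dir, ref2, p), "ghost")
})

test_that("shared k-mer tables cover all pairs", {
  seqs <- sim_seqs(8, len = 500, rate = 0.1, seed = 2)
  tb <- shared_kmer_table(seqs, k = 12)
  expect_identical(nrow(tb), 28L)
  expect_true(all(tb$shared_fraction >= 0 & tb$shared_fraction <= 1))
  self <- shared_kmer_table(seqs[c(1, 1, 2)] |>
                              setNames(c("a", "b", "c")), k = 8)
  expect_equal(self$shared_fraction[self$taxon1 == "a" &
                                    self$taxon2 == "b"], 1)
})
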