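# Scenario sweeps: simulate -> AF distance -> NJ -> normalized RF against
# the true tree, replicated over a parameter grid, plus the
# optimal-parameter selection rule and the empirical-data entry point.

#' Desk-scale simulation template
#'
#' A reduced-scale counterpart of the full simulation protocol (which uses
#' 25-35 genomes of 2000-3000 genes over 5000 iterations): 12 taxa,
#' ~150 genes of 200-400 nt, 500 iterations. Scenario sweeps at this scale
#' preserve the full protocol's per-gene event loads via
#' [lgt_rate_analog()] and [divergence_factor_analog()].
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
reduced_sim_config <- function(...) {
  defaults <- list(speciation_rate = 0.5, extinction_rate = 0.5,
                   iterations = 500, taxa_range = c(11, 13),
                   genes_range = c(140, 160),
                   gene_length_range = c(200, 400),
                   mutation_rate = c(0.4, 0.6), lgt_rate = 0,
                   rearrangement_rate = 0, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# number of iterations of the full protocol that desk-scale runs stand for
FULL_ITERATIONS <- 5000
# full-protocol LGT rate at which each gene is expected to be hit ~once
FULL_SATURATING_LGT <- 250

#' Scale a full-protocol LGT rate to a reduced configuration
#'
#' The full protocol attempts `l` transfers per iteration over 5000
#' iterations across ~30 genomes of ~2500 genes; at `l = 250` every gene is
#' expected to be hit about once. The analog attempt rate for a reduced
#' configuration preserves accepted transfers per gene over the run:
#' `l' = (l / 250) * N * G / (i * receptivity_mean)`.
#'
#' @param l Full-protocol mean LGT attempts per iteration.
#' @param config The reduced [sim_config()].
#' @return Scaled per-iteration attempt rate.
#' @export
lgt_rate_analog <- function(l, config) {
  n_taxa <- mean(config$taxa_range)
  n_genes <- mean(config$genes_range)
  acc <- max(config$receptivity$mean, 1e-6)
  (l / FULL_SATURATING_LGT) * n_taxa * n_genes / (config$iterations * acc)
}

#' @rdname lgt_rate_analog
#' @param d Full-protocol divergence factor (iterations).
#' @export
divergence_factor_analog <- function(d, config) {
  if (!is.finite(d)) return(Inf)
  d * config$iterations / FULL_ITERATIONS
}

# the divergence sweep's mutation levels are shorthand for sampling ranges
mutation_level_range <- function(m) {
  if (isTRUE(all.equal(m, 0.1))) c(0.01, 0.2)
  else if (isTRUE(all.equal(m, 0.5))) c(0.4, 0.6)
  else if (isTRUE(all.equal(m, 0.9))) c(0.8, 0.99)
  else m
}

SCENARIOS <- c("divergence", "lgt", "divergence_factor", "rearrangement")

# apply one grid value of a scenario sweep to a config template
scenario_apply <- function(scenario, value, config) {
  switch(scenario,
    divergence = {
      config$mutation_rate <- mutation_level_range(value)
      config$lgt_rate <- lgt_rate_analog(5, config)
      config
    },
    lgt = {
      config$lgt_rate <- lgt_rate_analog(value, config)
      config
    },
    divergence_factor = {
      config$lgt_rate <- lgt_rate_analog(5, config)
      config$divergence_factor <- divergence_factor_analog(value, config)
      config
    },
    rearrangement = {
      config$extinction_rate <- 0.1
      config$mutation_rate <- 0.5
      config$rearrangement_rate <- value
      config
    },
    stop("unknown scenario: ", scenario))
}

key_param <- function(p) {
  switch(p$method, d2 = , cvt = , ffp = p$k, cophylog = p$K,
         spaced = p$n_patterns, kmacs = p$mm, 0L)
}

#' Run a scenario sweep
#'
#' For every grid value and replicate: simulate a genome set, compute each
#' requested AF distance matrix, build the NJ tree and score it against the
#' true tree with the normalized Robinson-Foulds distance. Method failures
#' on a replicate (e.g. co-phylog with no shared contexts at extreme
#' divergence) are recorded and excluded from the aggregates.
#'
#' @param scenario One of `"divergence"`, `"lgt"`, `"divergence_factor"`,
#'   `"rearrangement"`. Grid values are on the full-protocol scale (`m`
#'   levels, `l`, `d`, or `r`) and are translated to the reduced
#'   configuration internally.
#' @param grid Numeric vector of swept values.
#' @param methods Named list of [af_params()] (names label the settings,
#'   e.g. `list(cophylog_K8 = af_params("cophylog", K = 8))`).
#' @param replicates Simulated sets per grid value.
#' @param config Simulation template, default [reduced_sim_config()].
#' @param seed Master seed; every replicate's simulation seed derives from
#'   it deterministically.
#' @return A `scenario_result`: list with `results` (one row per grid value
#'   x replicate x method), `summary` (mean and sd of RF per grid value and
#'   method, with failure counts) and the call ingredients.
#' @export
run_scenario <- function(scenario, grid, methods, replicates = 10,
                         config = reduced_sim_config(), seed = 1L) {
  scenario <- match.arg(scenario, SCENARIOS)
  stopifnot(length(grid) >= 1, length(methods) >= 1,
            !is.null(names(methods)))
  rows <- list()
  for (gi in seq_along(grid)) {
    cfg_g <- scenario_apply(scenario, grid[gi], config)
    for (rep in seq_len(replicates)) {
      cfg_g$seed <- as.integer((seed * 100003 + gi * 1009 + rep) %%
                                 .Machine$integer.max)
      gs <- evolve(cfg_g)
      seqs <- genome_strings(gs)
      for (mi in seq_along(methods)) {
        rf <- NA_real_; err <- ""
        res <- tryCatch({
          tr <- neighbor_joining(distance_matrix(seqs, methods[[mi]]))
          rf_normalized(tr, gs$tree)
        }, error = function(e) conditionMessage(e))
        if (is.numeric(res)) rf <- res else err <- res
        rows[[length(rows) + 1]] <- data.frame(
          scenario = scenario, grid = grid[gi], replicate = rep,
          method = names(methods)[mi], rf = rf, error = err,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- aggregate_scenario(results)
  structure(list(scenario = scenario, grid = grid, methods = methods,
                 replicates = replicates, seed = seed,
                 results = results, summary = summary),
            class = "scenario_result")
}

aggregate_scenario <- function(results) {
  key <- interaction(results$grid, results$method, drop = TRUE)
  out <- do.call(rbind, lapply(split(results, key), function(d) {
    ok <- d$rf[!is.na(d$rf)]
    data.frame(scenario = d$scenario[1], grid = d$grid[1],
               method = d$method[1],
               mean_rf = if (length(ok)) mean(ok) else NA_real_,
               sd_rf = if (length(ok) > 1) sd(ok) else 0,
               n = length(ok), n_failed = sum(is.na(d$rf)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$method, out$grid), ]
  rownames(out) <- NULL
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario_result:", x$scenario, "sweep over",
      paste(x$grid, collapse = ", "), "(", x$replicates, "replicates )\n")
  print(x$summary)
  invisible(x)
}

#' Optimal parameter setting per method
#'
#' Implements the selection rule used throughout the sweeps: for each
#' method, the candidate setting minimizing the grand mean of the per-grid
#' mean RF across all grid values wins; ties go to the smaller key
#' parameter (k / K / n / mm).
#'
#' @param sr A `scenario_result` from [run_scenario()] whose `methods`
#'   contain one or more candidate settings per method.
#' @return Named list, one entry per method, each with `label`, `params`
#'   and `grand_mean_rf`.
#' @export
select_optimal_params <- function(sr) {
  stopifnot(inherits(sr, "scenario_result"))
  s <- sr$summary
  grand <- vapply(names(sr$methods), function(lab) {
    rows <- s[s$method == lab, ]
    missing <- setdiff(sr$grid, rows$grid)
    if (length(missing) || anyNA(rows$mean_rf))
      stop("incomplete grid for ", lab, ": missing or failed cells at ",
           paste(union(missing, rows$grid[is.na(rows$mean_rf)]),
                 collapse = ", "))
    mean(rows$mean_rf)
  }, 0)
  meths <- vapply(sr$methods, `[[`, "", "method")
  out <- list()
  for (m in unique(meths)) {
    cand <- names(sr$methods)[meths == m]
    g <- grand[cand]
    kp <- vapply(sr$methods[cand], key_param, 0L)
    best <- cand[order(g, kp)][1]
    out[[m]] <- list(label = best, params = sr$methods[[best]],
                     grand_mean_rf = unname(g[best]))
  }
  out
}

#' Write scenario results to TSV
#'
#' @param sr A `scenario_result`.
#' @param dir Output directory (created if missing).
#' @return Paths of the written files (long-format `results.tsv` and
#'   aggregated `summary.tsv`), invisibly.
#' @export
report <- function(sr, dir) {
  stopifnot(inherits(sr, "scenario_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- sr$results[order(sr$results$grid, sr$results$method,
                          sr$results$replicate), ]
  p1 <- file.path(dir, "results.tsv")
  p2 <- file.path(dir, "summary.tsv")
  write.table(res, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sr$summary, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(results = p1, summary = p2))
}

read_fasta_genomes <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && dir.exists(fasta)) {
    files <- list.files(fasta, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files found in ", fasta)
    out <- vapply(files, function(f) {
      paste(dnabin_to_string(ape::read.FASTA(f)), collapse = "")
    }, "")
    names(out) <- sub("\\.(fa|fasta|fna)$", "", basename(files))
    out
  } else if (is.character(fasta) && length(fasta) == 1 &&
             file.exists(fasta)) {
    d <- dnabin_to_string(ape::read.FASTA(fasta))
    names(d) <- vapply(strsplit(names(d), "\\s+"), `[[`, "", 1)
    d
  } else {
    as_genome_seqs(fasta)
  }
}

#' Empirical-mode analysis of a genome set against a reference tree
#'
#' Reads whole-genome FASTA input, computes the AF distance matrix and NJ
#' tree, optionally attaches jackknife support, and scores the tree against
#' the supplied reference with the normalized Robinson-Foulds distance.
#'
#' @param fasta Directory of per-genome FASTA files, a single multi-FASTA
#'   (one record per genome), or a named character vector of sequences.
#' @param reference Reference tree: file path, Newick string, or
#'   [ape::phylo].
#' @param params An [af_params()].
#' @param jk A [jackknife_config()], or `NULL` to skip node support.
#' @param name_map Optional named character vector mapping FASTA record
#'   names to reference leaf names.
#' @return List with `tree` (support-annotated when jackknifed), `matrix`,
#'   `rf` (normalized RF against the reference) and `reference`.
#' @export
run_empirical <- function(fasta, reference, params, jk = NULL,
                          name_map = NULL) {
  seqs <- read_fasta_genomes(fasta)
  if (!is.null(name_map)) {
    miss <- setdiff(names(seqs), names(name_map))
    if (length(miss)) stop("name_map lacks entries for: ",
                           paste(miss, collapse = ", "))
    names(seqs) <- unname(name_map[names(seqs)])
  }
  ref <- if (inherits(reference, "phylo")) reference
         else if (grepl("\\(", reference)) newick_read(text = reference)
         else newick_read(reference)
  miss <- setdiff(ref$tip.label, names(seqs))
  if (length(miss)) stop("reference leaves absent from FASTA input: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(seqs), ref$tip.label)
  if (length(extra)) stop("FASTA genomes absent from the reference: ",
                          paste(extra, collapse = ", "))
  m <- distance_matrix(seqs, params)
  tree <- if (is.null(jk)) neighbor_joining(m)
          else jackknife_pipeline(seqs, params, jk)
  list(tree = tree, matrix = m, rf = rf_normalized(tree, ref),
       reference = ref)
}

#' Pairwise shared k-mer fraction table
#'
#' @param genomes Named character vector of genome sequences (or a
#'   `genome_set`).
#' @param k Word length (the shared-12-mer analyses use `k = 12`).
#' @param both_strands Count both strands.
#' @return Data frame with one row per unordered pair and the Jaccard
#'   fraction of shared distinct k-mers.
#' @export
shared_kmer_table <- function(genomes, k = 12L, both_strands = TRUE) {
  seqs <- as_genome_seqs(genomes)
  n <- length(seqs)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(
    taxon1 = names(seqs)[pairs[, 1]],
    taxon2 = names(seqs)[pairs[, 2]],
    shared_fraction = apply(pairs, 1, function(ij)
      shared_kmer_fraction(seqs[[ij[1]]], seqs[[ij[2]]], k, both_strands)),
    stringsAsFactors = FALSE)
}
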