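# Event-driven genome evolution along a sampled birth-death tree.
#
# Sequences are evolved lazily per gene: each gene carries the time it was
# last updated, and substitutions are applied in bulk over the elapsed
# interval (GTR+Gamma transition probabilities). Whole genomes are brought
# up to date at every speciation node (so that shared history stays shared)
# and at the leaves; in between, only genes touched by LGT are advanced.

BASES <- c("A", "C", "G", "T")

rint <- function(r) if (r[1] >= r[2]) r[1] else sample(seq.int(r[1], r[2]), 1L)

draw_receptivity <- function(cfg) {
  r <- cfg$receptivity
  if (r$max <= r$min) return(r$min)
  f <- (r$mean - r$min) / (r$max - r$min)
  conc <- 4  # mild concentration around the target mean
  r$min + (r$max - r$min) * rbeta(1L, f * conc, (1 - f) * conc)
}

advance_gene <- function(g, t_to, mu, grates, eig) {
  dt <- t_to - g$t
  g$t <- t_to
  if (dt <= 0 || mu <= 0) return(g)
  for (cc in unique(g$cats)) {
    idx <- which(g$cats == cc)
    P <- gtr_ptrans(eig, mu * grates[cc] * dt)
    cum <- P
    cum[, 2] <- cum[, 1] + P[, 2]
    cum[, 3] <- cum[, 2] + P[, 3]
    cum[, 4] <- 1
    u <- runif(length(idx))
    cm <- cum[g$seq[idx], , drop = FALSE]
    g$seq[idx] <- 1L + as.integer(rowSums(cm < u))
  }
  g
}

# LGT arrival: replace the recipient's same-family gene when present,
# otherwise insert at a uniformly random position
transfer_gene_into <- function(rgenes, g) {
  fam <- vapply(rgenes, `[[`, 0L, "family")
  hit <- which(fam == g$family)
  if (length(hit) > 0) {
    rgenes[[hit[1]]] <- g
    rgenes
  } else {
    append(rgenes, list(g), after = rint(c(0L, length(rgenes))))
  }
}

advance_genome <- function(genome, t_to, mu, grates, eig) {
  genome$genes <- lapply(genome$genes, advance_gene, t_to = t_to, mu = mu,
                         grates = grates, eig = eig)
  genome
}

# excise `span` genes starting at `start`, reverse their order and
# orientations, and reinsert after position `insert_after` (0-based, counted
# on the shortened genome)
#' Apply a single inverted-translocation event to a gene list
#'
#' A contiguous block of genes is excised, its gene order reversed and every
#' orientation flipped (the block is re-read on the opposite strand), and
#' the block is reinserted elsewhere. The gene-family multiset is conserved.
#'
#' @param genes A list of gene records (each with at least `orientation`).
#' @param start 1-based index of the first gene of the block.
#' @param span Number of genes in the block.
#' @param insert_after 0-based position in the shortened gene list after
#'   which the block is reinserted (0 = at the front).
#' @return The rearranged gene list.
#' @export
invert_translocation <- function(genes, start, span, insert_after) {
  n <- length(genes)
  stopifnot(start >= 1, span >= 1, start + span - 1 <= n,
            insert_after >= 0, insert_after <= n - span)
  block <- rev(genes[start:(start + span - 1)])
  block <- lapply(block, function(g) { g$orientation <- -g$orientation; g })
  rest <- genes[-(start:(start + span - 1))]
  append(rest, block, after = insert_after)
}

#' Apply a run's worth of inverted translocations to one genome
#'
#' Draws the number of events from a Poisson law calibrated so that at rate
#' `r = 1` the blocks moved over the run cover about
#' `rearrangement_calibration` (default 20 percent) of the genome length;
#' each event moves `Uniform{1..max_genes_per_event}` contiguous genes.
#'
#' @param genome A genome record (list with `genes`).
#' @param r Rearrangement rate (0 disables).
#' @param max_genes_per_event Maximum block size in genes.
#' @param calibration Affected-length fraction per unit `r`.
#' @param seed Optional integer seed.
#' @return A list with the rearranged `genome` and an `events` data frame
#'   (start index, span, insertion point).
#' @export
#' @examples
#' g <- list(taxon_id = "x", genes = lapply(1:10, function(i)
#'   list(id = i, family = i, seq = c(1L, 2L), cats = c(1L, 1L),
#'        t = 0, orientation = 1L)))
#' rearrange(g, r = 1, seed = 1)$events
rearrange <- function(genome, r, max_genes_per_event = 20L,
                      calibration = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ngenes <- length(genome$genes)
  stopifnot(ngenes >= 2)
  ev <- data.frame(start = integer(), span = integer(),
                   insert_after = integer())
  if (r > 0) {
    ebar <- (1 + min(max_genes_per_event, ngenes - 1L)) / 2
    n_events <- rpois(1L, r * calibration * ngenes / ebar)
    for (i in seq_len(n_events)) {
      drawn <- draw_rearrangement(genome$genes, max_genes_per_event)
      genome$genes <- drawn$genes
      ev <- rbind(ev, drawn$event)
    }
  }
  list(genome = genome, events = ev)
}

draw_rearrangement <- function(genes, max_genes_per_event) {
  n <- length(genes)
  span <- rint(c(1L, min(max_genes_per_event, n - 1L)))
  start <- rint(c(1L, n - span + 1L))
  insert_after <- rint(c(0L, n - span))
  list(genes = invert_translocation(genes, start, span, insert_after),
       event = data.frame(start = start, span = span,
                          insert_after = insert_after))
}

#' Simulate a genome set
#'
#' Runs the full simulator: samples a birth-death reference tree, seeds a
#' root genome of random genes, and evolves it down the tree under
#' GTR+Gamma substitution, lateral genetic transfer (LGT) and
#' inverted-translocation rearrangement, logging every event.
#'
#' LGT attempts arrive as a Poisson process with mean `lgt_rate` per
#' iteration across the set; each attempt draws an ordered donor/recipient
#' pair uniformly among the lineages alive at that time and succeeds only if
#' (i) the pair's divergence (iterations since their most recent common
#' ancestor) does not exceed `divergence_factor` and (ii) a uniform draw
#' falls below the recipient's receptivity. An accepted event copies one
#' random donor gene, replacing the recipient's copy of the same family when
#' one exists and inserting at a random position otherwise.
#'
#' @param config A [sim_config()] object; `config$seed` drives every random
#'   draw.
#' @return A `genome_set`: list with `genomes` (per extant taxon: ordered
#'   gene lists and receptivity), `tree` (the true tree, see
#'   [sample_tree()]), `log` (LGT attempts, rearrangement events, extinct
#'   lineage count, realized mutation rate) and `config`.
#' @seealso [genome_strings()], [write_genome_set()]
#' @export
#' @examples
#' cfg <- sim_config(taxa_range = c(4, 6), genes_range = c(5, 6),
#'                   gene_length_range = c(60, 80), iterations = 100,
#'                   mutation_rate = 0.3, lgt_rate = 0.05, seed = 42)
#' gs <- evolve(cfg)
#' names(gs$genomes)
evolve <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  tree <- sample_tree(cfg, seed = NULL)
  ntip <- length(tree$tip.label)
  node_time <- attr(tree, "node_time")
  t_root <- attr(tree, "t_root")
  t_end <- cfg$iterations
  root <- ntip + 1L

  M <- ape::mrca(tree, full = TRUE)
  mrca_time <- matrix(node_time[M], nrow(M))

  m <- draw_mutation_rate(cfg)
  # clock anchored to the extant tree's depth: root-to-tip substitution
  # load is m * mutation_calibration regardless of where the MRCA falls
  span <- max(t_end - t_root, 1e-9)
  mu <- m * cfg$mutation_calibration / span
  Q <- build_gtr_matrix(cfg$gtr_rates, cfg$base_freqs)
  eig <- gtr_eigen(Q, cfg$base_freqs)
  grates <- gamma_category_rates(cfg$gamma_shape, cfg$gamma_categories)

  # root genome
  ngenes <- rint(cfg$genes_range)
  glens <- cfg$gene_length_range[1] +
    sample.int(cfg$gene_length_range[2] - cfg$gene_length_range[1] + 1L,
               ngenes, replace = TRUE) - 1L
  root_genes <- lapply(seq_len(ngenes), function(i) {
    list(id = paste0("g", i), family = i,
         seq = sample.int(4L, glens[i], replace = TRUE,
                          prob = cfg$base_freqs),
         cats = sample.int(cfg$gamma_categories, glens[i], replace = TRUE),
         t = t_root, orientation = 1L)
  })

  # lineage name: tip label for leaf edges, node id otherwise
  lin_name <- function(id)
    if (id <= ntip) tree$tip.label[id] else paste0("n", id)

  # --- event schedule -----------------------------------------------------
  internal <- setdiff(seq_len(ntip + tree$Nnode), seq_len(ntip))
  internal <- setdiff(internal, root)
  spec_t <- node_time[internal]

  # LGT attempts arrive at rate lgt_rate per iteration while the set has
  # at least two lineages, i.e. over (t_root, t_end]
  n_lgt_total <- if (cfg$lgt_rate > 0) rpois(1L, cfg$lgt_rate * span) else 0L
  lgt_t <- sort(runif(n_lgt_total, t_root, t_end))

  rr <- cfg$rearrangement_rate
  re_edge <- integer(); re_t <- numeric()
  if (rr > 0) {
    ebar <- (1 + min(cfg$max_genes_per_event, max(ngenes - 1L, 1L))) / 2
    run_rate <- rr * cfg$rearrangement_calibration * ngenes / ebar
    for (k in seq_len(nrow(tree$edge))) {
      child <- tree$edge[k, 2]
      tp <- node_time[tree$edge[k, 1]]; tc <- node_time[child]
      nev <- rpois(1L, run_rate * (tc - tp) / span)
      if (nev > 0) {
        re_edge <- c(re_edge, rep(child, nev))
        re_t <- c(re_t, runif(nev, tp, tc))
      }
    }
  }

  ev_time <- c(spec_t, lgt_t, re_t)
  ev_type <- rep(c("S", "L", "R"),
                 c(length(spec_t), length(lgt_t), length(re_t)))
  ev_node <- c(internal, rep(NA_integer_, length(lgt_t)), re_edge)
  ord <- order(ev_time)
  ev_time <- ev_time[ord]; ev_type <- ev_type[ord]; ev_node <- ev_node[ord]

  # --- logs ---------------------------------------------------------------
  nl <- length(lgt_t)
  lg <- list(iteration = numeric(nl), donor = character(nl),
             recipient = character(nl), family_id = integer(nl),
             accepted = logical(nl), reason = character(nl))
  li <- 0L
  rl <- list(iteration = numeric(0), taxon = character(0),
             start = integer(0), span = integer(0),
             insert_after = integer(0))

  # --- state --------------------------------------------------------------
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  state <- vector("list", ntip + tree$Nnode)
  for (ch in kids_of[[as.character(root)]]) {
    state[[ch]] <- list(genes = root_genes,
                        receptivity = draw_receptivity(cfg))
  }
  alive <- kids_of[[as.character(root)]]
  gene_counter <- ngenes

  for (j in seq_along(ev_time)) {
    t <- ev_time[j]
    type <- ev_type[j]
    if (type == "S") {
      k <- ev_node[j]
      gk <- state[[k]]
      gk$genes <- lapply(gk$genes, advance_gene, t_to = t, mu = mu,
                         grates = grates, eig = eig)
      for (ch in kids_of[[as.character(k)]]) {
        state[[ch]] <- list(genes = gk$genes,
                            receptivity = draw_receptivity(cfg))
      }
      state[k] <- list(NULL)
      alive <- c(alive[alive != k], kids_of[[as.character(k)]])
    } else if (type == "L") {
      pair <- alive[sample.int(length(alive), 2L)]
      donor <- pair[1]; recip <- pair[2]
      li <- li + 1L
      lg$iteration[li] <- t
      lg$donor[li] <- lin_name(donor)
      lg$recipient[li] <- lin_name(recip)
      div <- t - mrca_time[donor, recip]
      dgenes <- state[[donor]]$genes
      gi <- sample.int(length(dgenes), 1L)
      lg$family_id[li] <- dgenes[[gi]]$family
      if (is.finite(cfg$divergence_factor) && div > cfg$divergence_factor) {
        lg$accepted[li] <- FALSE; lg$reason[li] <- "divergence"
      } else if (runif(1) > state[[recip]]$receptivity) {
        lg$accepted[li] <- FALSE; lg$reason[li] <- "receptivity"
      } else {
        g <- advance_gene(dgenes[[gi]], t, mu, grates, eig)
        state[[donor]]$genes[[gi]] <- g
        gene_counter <- gene_counter + 1L
        g$id <- paste0("g", g$family, "_x", gene_counter)
        state[[recip]]$genes <- transfer_gene_into(state[[recip]]$genes, g)
        lg$accepted[li] <- TRUE; lg$reason[li] <- ""
      }
    } else {  # rearrangement
      e <- ev_node[j]
      if (length(state[[e]]$genes) >= 2) {
        drawn <- draw_rearrangement(state[[e]]$genes, cfg$max_genes_per_event)
        state[[e]]$genes <- drawn$genes
        rl$iteration <- c(rl$iteration, t)
        rl$taxon <- c(rl$taxon, lin_name(e))
        rl$start <- c(rl$start, drawn$event$start)
        rl$span <- c(rl$span, drawn$event$span)
        rl$insert_after <- c(rl$insert_after, drawn$event$insert_after)
      }
    }
  }

  genomes <- vector("list", ntip)
  for (leaf in seq_len(ntip)) {
    gk <- state[[leaf]]
    gk$genes <- lapply(gk$genes, advance_gene, t_to = t_end, mu = mu,
                       grates = grates, eig = eig)
    genomes[[leaf]] <- list(taxon_id = tree$tip.label[leaf],
                            genes = gk$genes,
                            receptivity = gk$receptivity)
  }
  names(genomes) <- tree$tip.label

  lgt_df <- data.frame(iteration = lg$iteration[seq_len(li)],
                       donor = lg$donor[seq_len(li)],
                       recipient = lg$recipient[seq_len(li)],
                       family_id = lg$family_id[seq_len(li)],
                       accepted = lg$accepted[seq_len(li)],
                       reason = lg$reason[seq_len(li)],
                       stringsAsFactors = FALSE)
  re_df <- data.frame(iteration = rl$iteration, taxon = rl$taxon,
                      start = rl$start, span = rl$span,
                      insert_after = rl$insert_after,
                      stringsAsFactors = FALSE)

  structure(list(genomes = genomes, tree = tree,
                 log = list(lgt_events = lgt_df,
                            rearrangement_events = re_df,
                            n_extinct = attr(tree, "n_extinct"),
                            mutation_rate = m),
                 config = cfg),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x$genomes), "genomes,",
      length(x$genomes[[1]]$genes), "genes in genome 1;",
      nrow(x$log$lgt_events), "LGT attempts,",
      nrow(x$log$rearrangement_events), "rearrangement events\n")
  invisible(x)
}

#' Concatenated genome sequences of a genome set
#'
#' Genes are concatenated in genome order; genes on the minus strand
#' contribute their reverse complement.
#'
#' @param gs A `genome_set` from [evolve()], or a single genome record.
#' @return Named character vector of genome strings.
#' @export
genome_strings <- function(gs) {
  gl <- if (inherits(gs, "genome_set")) gs$genomes else gs
  out <- vapply(gl, function(g) {
    pieces <- vapply(g$genes, function(gene) {
      s <- paste(BASES[gene$seq], collapse = "")
      if (gene$orientation < 0) cpp_revcomp(s) else s
    }, "")
    paste(pieces, collapse = "")
  }, "")
  names(out) <- vapply(gl, `[[`, "", "taxon_id")
  out
}
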