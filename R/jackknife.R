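# Fragment-deletion jackknife for alignment-free trees: from each genome a
# fixed fraction is removed as fixed-length fragments, a tree is built per
# pseudo-replicate, and the test tree's splits are scored by how often the
# replicates contain them.

#' Jackknife configuration
#'
#' @param rate Fraction of each genome to delete (default 0.4).
#' @param fragment_length Length in nt of each deleted fragment
#'   (default 100).
#' @param replicates Number of pseudo-replicates `B` (default 100).
#' @param seed Integer seed for the deletion positions.
#' @return An object of class `jackknife_config`.
#' @export
#' @examples
#' jackknife_config(replicates = 20)
jackknife_config <- function(rate = 0.4, fragment_length = 100L,
                             replicates = 100L, seed = 1L) {
  stopifnot(rate > 0, rate < 1, fragment_length >= 1, replicates >= 1)
  structure(list(rate = rate, fragment_length = as.integer(fragment_length),
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "jackknife_config")
}

#' Delete random fragments from a sequence
#'
#' Performs `n_del = floor(L * rate / fragment_length)` sequential deletions
#' of `fragment_length` nt at uniformly random positions; each deletion
#' shortens the sequence before the next position is drawn. The result has
#' exactly `L - n_del * fragment_length` nt.
#'
#' @param sequence A single character string.
#' @param rate Deleted fraction of the original length.
#' @param fragment_length Fragment size in nt.
#' @param seed Optional integer seed (`NULL`: use the current RNG stream).
#' @return The jackknifed sequence.
#' @export
#' @examples
#' nchar(delete_fragments(strrep("ACGT", 2500), 0.4, 100, seed = 1))  # 6000
delete_fragments <- function(sequence, rate = 0.4, fragment_length = 100L,
                             seed = NULL) {
  check_seq(sequence)
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(sequence)
  n_del <- floor(L * rate / fragment_length)
  if (n_del == 0) return(sequence)
  if (L - n_del * fragment_length < 1)
    stop("sequence too short to delete ", n_del, " fragments of ",
         fragment_length, " nt")
  for (i in seq_len(n_del)) {
    Lc <- nchar(sequence)
    start <- sample.int(Lc - fragment_length + 1L, 1L)
    sequence <- paste0(substr(sequence, 1L, start - 1L),
                       substr(sequence, start + fragment_length, Lc))
  }
  sequence
}

#' Generate jackknife pseudo-replicate genome sets
#'
#' Applies [delete_fragments()] independently to every genome, `replicates`
#' times; replicates are mutually independent given the seed stream.
#'
#' @param genomes Named character vector of genome sequences (or a
#'   `genome_set`).
#' @param config A [jackknife_config()].
#' @return List of `replicates` named character vectors.
#' @export
pseudo_replicates <- function(genomes, config = jackknife_config()) {
  seqs <- as_genome_seqs(genomes)
  set.seed(config$seed)
  lapply(seq_len(config$replicates), function(b) {
    vapply(seqs, delete_fragments, "", rate = config$rate,
           fragment_length = config$fragment_length)
  })
}

#' Jackknife node support for a test tree
#'
#' For every internal edge of the test tree, support is 100 times the
#' fraction of replicate trees containing that bipartition, rounded to the
#' nearest integer and written into the test tree's node labels.
#'
#' @param test_tree The tree built from the full genomes.
#' @param replicate_trees List of trees built from pseudo-replicates (same
#'   leaf set).
#' @return `test_tree` with integer support values as `node.label`.
#' @export
jackknife_support <- function(test_tree, replicate_trees) {
  for (tr in replicate_trees) check_same_leaves(test_tree, tr)
  st <- split_table(test_tree)
  counts <- numeric(length(st$keys))
  for (tr in replicate_trees) {
    counts <- counts + (st$keys %in% split_table(tr)$keys)
  }
  supp <- as.integer(round(100 * counts / length(replicate_trees)))
  labs <- rep("", test_tree$Nnode)
  ntip <- length(test_tree$tip.label)
  labs[st$nodes - ntip] <- as.character(supp)
  test_tree$node.label <- labs
  test_tree
}

#' Full jackknife pipeline
#'
#' Builds the test tree from the complete genomes, then `replicates`
#' neighbour-joining trees from fragment-deleted pseudo-replicates with the
#' same AF method, and annotates the test tree with jackknife support.
#'
#' @param genomes Named character vector of genome sequences or a
#'   `genome_set`.
#' @param params An [af_params()] choosing the AF distance.
#' @param config A [jackknife_config()].
#' @return The support-annotated test tree ([ape::phylo]); the replicate
#'   trees are attached as attribute `replicate_trees`.
#' @export
jackknife_pipeline <- function(genomes, params,
                               config = jackknife_config()) {
  seqs <- as_genome_seqs(genomes)
  if (length(seqs) < 4) stop("jackknife pipeline needs at least 4 genomes")
  test_tree <- neighbor_joining(distance_matrix(seqs, params))
  reps <- pseudo_replicates(seqs, config)
  rep_trees <- vector("list", length(reps))
  for (b in seq_along(reps)) {
    rep_trees[[b]] <- tryCatch(
      neighbor_joining(distance_matrix(reps[[b]], params)),
      error = function(e) stop("replicate ", b, " failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  out <- jackknife_support(test_tree, rep_trees)
  attr(out, "replicate_trees") <- rep_trees
  out
}
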