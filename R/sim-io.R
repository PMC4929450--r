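# On-disk layout for a simulated genome set:
#   genomes.fasta            one record per taxon (concatenated genome)
#   genes/<taxon>.fasta      one record per gene (id, family, orientation)
#   reference_tree.nwk       the true tree
#   lgt_events.tsv, rearrangement_events.tsv
#   config.json

string_to_dnabin <- function(x) {
  ape::as.DNAbin(lapply(x, function(s) strsplit(tolower(s), "")[[1]]))
}

dnabin_to_string <- function(d) {
  vapply(as.character(d), function(v) toupper(paste(v, collapse = "")), "")
}

#' Write a simulated genome set to a directory
#'
#' Emits whole-genome and per-gene multi-FASTA files, the reference tree in
#' Newick, the event logs as TSV and the configuration as JSON. The output
#' round-trips losslessly through [read_genome_set()].
#'
#' @param gs A `genome_set` from [evolve()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(gs, dir) {
  stopifnot(inherits(gs, "genome_set"))
  if (any(vapply(gs$genomes, function(g) length(g$genes), 0L) == 0))
    stop("every genome must contain at least one gene")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "genes"), showWarnings = FALSE)

  ape::write.FASTA(string_to_dnabin(genome_strings(gs)),
                   file.path(dir, "genomes.fasta"))
  for (g in gs$genomes) {
    seqs <- vapply(g$genes, function(gene)
      paste(BASES[gene$seq], collapse = ""), "")
    names(seqs) <- vapply(g$genes, function(gene)
      sprintf("%s family=%d orientation=%s", gene$id, gene$family,
              ifelse(gene$orientation > 0, "+", "-")), "")
    ape::write.FASTA(string_to_dnabin(seqs),
                     file.path(dir, "genes", paste0(g$taxon_id, ".fasta")))
  }
  newick_write(gs$tree, file.path(dir, "reference_tree.nwk"))
  write.table(gs$log$lgt_events, file.path(dir, "lgt_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gs$log$rearrangement_events,
              file.path(dir, "rearrangement_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- gs$config
  cfg$divergence_factor <- if (is.finite(cfg$divergence_factor))
    cfg$divergence_factor else "Inf"
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back a genome set directory
#'
#' @param dir A directory written by [write_genome_set()].
#' @return A list with `sequences` (named genome strings), `genes` (per
#'   taxon data frames of gene id, family, orientation and sequence),
#'   `tree`, `lgt_events`, `rearrangement_events` and `config`.
#' @export
read_genome_set <- function(dir) {
  seqs <- dnabin_to_string(ape::read.FASTA(file.path(dir, "genomes.fasta")))
  gene_files <- list.files(file.path(dir, "genes"), full.names = TRUE)
  genes <- lapply(gene_files, function(f) {
    d <- ape::read.FASTA(f)
    hdr <- strsplit(names(d), " ")
    data.frame(
      gene_id = vapply(hdr, `[[`, "", 1),
      family = as.integer(sub("family=", "",
                              vapply(hdr, `[[`, "", 2))),
      orientation = ifelse(sub("orientation=", "",
                               vapply(hdr, `[[`, "", 3)) == "+", 1L, -1L),
      sequence = unname(dnabin_to_string(d)),
      stringsAsFactors = FALSE)
  })
  names(genes) <- sub("\\.fasta$", "", basename(gene_files))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  if (identical(cfg$divergence_factor, "Inf")) cfg$divergence_factor <- Inf
  list(sequences = seqs, genes = genes,
       tree = newick_read(file.path(dir, "reference_tree.nwk"),
                          unroot = FALSE),
       lgt_events = read.table(file.path(dir, "lgt_events.tsv"),
                               sep = "\t", header = TRUE),
       rearrangement_events = read.table(
         file.path(dir, "rearrangement_events.tsv"),
         sep = "\t", header = TRUE),
       config = cfg)
}
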