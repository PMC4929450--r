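#' Configuration for a genome-set simulation
#'
#' Bundles every tunable of the genome evolution simulator: the birth-death
#' tree process, genome and gene sizes, the GTR+Gamma substitution model,
#' lateral genetic transfer (LGT) and inverted-translocation rearrangement.
#'
#' The simulator works on a discrete "iteration" time axis of length
#' `iterations`. The mutation rate `m` is calibrated so that the expected
#' per-site substitution load from the root of the extant tree to a leaf is
#' exactly `m * mutation_calibration`. The default calibration 0.25 places
#' the `m` sweep across the operating range of word lengths 8-16: `m = 0.5`
#' leaves exact 16-mer statistics informative while `m = 0.9` heavily
#' degrades them.
#'
#' @param speciation_rate,extinction_rate Relative birth-death propensities
#'   per lineage (dimensionless; the absolute per-iteration event
#'   probability is `rate * tree_event_scale`).
#' @param iterations Length of the run in iterations (time units).
#' @param taxa_range Integer vector `c(min, max)`: accepted extant leaf counts.
#' @param genes_range Integer `c(min, max)` genes per genome at the root.
#' @param gene_length_range Integer `c(min, max)` gene length in nt.
#' @param mutation_rate Scalar or range `c(min, max)`; a single value per run
#'   is drawn uniformly from a range.
#' @param mutation_calibration Expected root-to-tip substitutions per site at
#'   `m = 1` (see Details).
#' @param lgt_rate Mean number of LGT attempts in the set per iteration.
#' @param divergence_factor Maximum iterations separating donor and recipient
#'   from their most recent common ancestor for an LGT attempt to be
#'   acceptable; `Inf` disables the constraint.
#' @param receptivity Named list `min`, `mean`, `max` of per-genome LGT
#'   acceptance propensities in `[0, 1]`.
#' @param rearrangement_rate Inverted-translocation intensity `r`; `r = 1`
#'   rearranges about `rearrangement_calibration` of each genome's length
#'   over the run.
#' @param rearrangement_calibration Affected-length fraction per unit `r`
#'   (default 0.2, i.e. `r` in 0.01/0.10/1.00 affects ~0.2/2/20 percent).
#' @param max_genes_per_event Maximum genes per rearrangement block.
#' @param gtr_rates Named list of GTR exchangeabilities `a` (A-C), `b` (A-G),
#'   `c` (A-T), `d_rate` (C-G), `e` (C-T), `f` (G-T, reference rate).
#' @param base_freqs Stationary base frequencies (A, C, G, T).
#' @param gamma_shape Shape `alpha` of the gamma rate-heterogeneity model.
#' @param gamma_categories Number of discrete gamma categories.
#' @param tree_event_scale Per-iteration scaling of the birth-death
#'   propensities; `NULL` auto-calibrates so the expected extant count at the
#'   end of the run is near the middle of `taxa_range`.
#' @param seed Integer seed; every stochastic step of [evolve()] derives
#'   from it.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [evolve()], [sample_tree()]
#' @export
#' @examples
#' cfg <- sim_config(taxa_range = c(5, 7), genes_range = c(10, 12),
#'                   gene_length_range = c(100, 150), iterations = 100)
#' cfg$mutation_rate
sim_config <- function(speciation_rate = 0.5,
                       extinction_rate = 0.5,
                       iterations = 5000,
                       taxa_range = c(25, 35),
                       genes_range = c(2000, 3000),
                       gene_length_range = c(240, 1500),
                       mutation_rate = c(0.4, 0.6),
                       mutation_calibration = 0.25,
                       lgt_rate = 0,
                       divergence_factor = Inf,
                       receptivity = list(min = 0.2, mean = 0.5, max = 0.8),
                       rearrangement_rate = 0,
                       rearrangement_calibration = 0.2,
                       max_genes_per_event = 20,
                       gtr_rates = list(a = 0.987, b = 0.11, c = 0.218,
                                        d_rate = 0.243, e = 0.395, f = 1.0),
                       base_freqs = rep(0.25, 4),
                       gamma_shape = 1.0,
                       gamma_categories = 8,
                       tree_event_scale = NULL,
                       seed = 1L) {
  cfg <- list(
    speciation_rate = speciation_rate, extinction_rate = extinction_rate,
    iterations = iterations, taxa_range = as.integer(taxa_range),
    genes_range = as.integer(genes_range),
    gene_length_range = as.integer(gene_length_range),
    mutation_rate = mutation_rate,
    mutation_calibration = mutation_calibration,
    lgt_rate = lgt_rate, divergence_factor = divergence_factor,
    receptivity = receptivity,
    rearrangement_rate = rearrangement_rate,
    rearrangement_calibration = rearrangement_calibration,
    max_genes_per_event = as.integer(max_genes_per_event),
    gtr_rates = gtr_rates, base_freqs = base_freqs,
    gamma_shape = gamma_shape,
    gamma_categories = as.integer(gamma_categories),
    tree_event_scale = tree_event_scale, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param x A `sim_config` object.
#' @export
validate_sim_config <- function(x) {
  stopifnot(inherits(x, "sim_config"))
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < 1)
      stop(nm, " must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  rates <- c(x$speciation_rate, x$extinction_rate, x$lgt_rate,
             x$rearrangement_rate, x$mutation_rate)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (x$iterations <= 0) stop("iterations must be positive", call. = FALSE)
  chk_range(x$taxa_range, "taxa_range")
  chk_range(x$genes_range, "genes_range")
  chk_range(x$gene_length_range, "gene_length_range")
  if (!length(x$mutation_rate) %in% 1:2)
    stop("mutation_rate must be a scalar or c(min, max)", call. = FALSE)
  if (length(x$mutation_rate) == 2 &&
      x$mutation_rate[1] > x$mutation_rate[2])
    stop("mutation_rate range must have min <= max", call. = FALSE)
  if (abs(sum(x$base_freqs) - 1) > 1e-12)
    stop("base_freqs must sum to 1", call. = FALSE)
  if (any(x$base_freqs < 0)) stop("base_freqs must be >= 0", call. = FALSE)
  r <- x$receptivity
  if (!(r$min <= r$mean && r$mean <= r$max) ||
      r$min < 0 || r$max > 1)
    stop("receptivity must satisfy 0 <= min <= mean <= max <= 1",
         call. = FALSE)
  if (x$gamma_categories < 1)
    stop("gamma_categories must be >= 1", call. = FALSE)
  if (any(unlist(x$gtr_rates) < 0))
    stop("GTR exchangeabilities must be >= 0", call. = FALSE)
  if (x$max_genes_per_event < 1)
    stop("max_genes_per_event must be >= 1", call. = FALSE)
  x
}

# effective per-iteration, per-lineage birth/death probabilities
tree_event_probs <- function(cfg) {
  b <- cfg$speciation_rate
  e <- cfg$extinction_rate
  sc <- cfg$tree_event_scale
  if (is.null(sc)) {
    target <- mean(cfg$taxa_range)
    sc <- if (b > e) log(target) / ((b - e) * cfg$iterations)
          else target / (max(b, 1e-8) * cfg$iterations)
  }
  c(lambda = b * sc, mu = e * sc)
}

# one mutation rate per run, drawn uniformly if a range is given
draw_mutation_rate <- function(cfg) {
  m <- cfg$mutation_rate
  if (length(m) == 2L) runif(1, m[1], m[2]) else m
}
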