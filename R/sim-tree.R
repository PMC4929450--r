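#' Sample a birth-death reference tree
#'
#' Simulates a forward-time birth-death process on the iteration axis
#' (Gillespie algorithm with per-lineage event probabilities
#' `rate * tree_event_scale`), rejection-sampling runs until the number of
#' lineages extant at `iterations` falls inside `taxa_range`. The returned
#' tree is the reconstructed tree of the extant taxa: extinct side branches
#' are pruned but counted.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param max_attempts Maximum rejection-sampling attempts before the
#'   configuration is declared infeasible.
#' @return An [ape::phylo] object with branch lengths in iterations and
#'   attributes `node_time` (absolute time of every node, leaves at
#'   `iterations`), `t_root` (time of the extant MRCA) and `n_extinct`
#'   (pruned extinct lineages).
#' @export
#' @examples
#' cfg <- sim_config(taxa_range = c(5, 8), iterations = 200, seed = 7)
#' tr <- sample_tree(cfg)
#' ape::Ntip(tr)
sample_tree <- function(config, seed = config$seed, max_attempts = 10000L) {
  cfg <- validate_sim_config(config)
  if (cfg$taxa_range[2] < 2)
    stop("taxa_range must allow at least 2 extant taxa")
  if (!is.null(seed)) set.seed(seed)
  pr <- tree_event_probs(cfg)
  t_end <- cfg$iterations
  cap <- 5L * cfg$taxa_range[2]  # abort runs that explode
  for (attempt in seq_len(max_attempts)) {
    run <- bd_forward(pr["lambda"], pr["mu"], t_end, cap)
    if (is.null(run)) next
    n_ext <- sum(run$fate == "extant")
    if (n_ext < max(2L, cfg$taxa_range[1]) || n_ext > cfg$taxa_range[2])
      next
    return(bd_to_phylo(run, t_end))
  }
  stop("birth-death process failed to reach taxa_range in ",
       max_attempts, " attempts; configuration looks infeasible")
}

# forward Gillespie birth-death run; returns lineage records or NULL if the
# process dies out or explodes past `cap` concurrent lineages
bd_forward <- function(lambda, mu, t_end, cap) {
  nmax <- 4L * cap + 8L
  parent <- integer(nmax); t_birth <- numeric(nmax); t_death <- numeric(nmax)
  fate <- character(nmax)
  n <- 1L
  parent[1] <- 0L; t_birth[1] <- 0; fate[1] <- "alive"
  alive <- 1L
  t <- 0
  p_spec <- lambda / (lambda + mu)
  repeat {
    k <- length(alive)
    if (k == 0L) return(NULL)
    if (k > cap) return(NULL)
    total <- k * (lambda + mu)
    if (total <= 0) break
    t <- t + rexp(1, total)
    if (t >= t_end) break
    pick <- alive[sample.int(k, 1L)]
    if (runif(1) < p_spec) {
      if (n + 2L > nmax) return(NULL)
      for (j in 1:2) {
        n <- n + 1L
        parent[n] <- pick; t_birth[n] <- t; fate[n] <- "alive"
      }
      t_death[pick] <- t; fate[pick] <- "split"
      alive <- c(alive[alive != pick], n - 1L, n)
    } else {
      t_death[pick] <- t; fate[pick] <- "dead"
      alive <- alive[alive != pick]
    }
  }
  t_death[alive] <- t_end
  fate[alive] <- "extant"
  list(parent = parent[1:n], t_birth = t_birth[1:n],
       t_death = t_death[1:n], fate = fate[1:n])
}

# prune to lineages with extant descendants and emit an ape tree
bd_to_phylo <- function(run, t_end) {
  n <- length(run$fate)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    p <- run$parent[i]
    if (p > 0L) kids[[p]] <- c(kids[[p]], i)
  }
  keep <- logical(n)
  # lineages sorted by birth time descending ensures children first
  for (i in order(run$t_birth, decreasing = TRUE)) {
    keep[i] <- run$fate[i] == "extant" ||
      (length(kids[[i]]) > 0 && any(keep[kids[[i]]]))
  }
  n_extinct <- sum(run$fate == "dead")
  labels <- character(n)
  labels[run$fate == "extant"] <- paste0("t", seq_len(sum(run$fate == "extant")))
  # recursive newick over kept lineages, merging unary chains
  descend <- function(l) {
    t_top <- run$t_birth[l]
    repeat {
      kk <- kids[[l]]
      kk <- kk[keep[kk]]
      if (length(kk) == 1L) { l <- kk; next }
      break
    }
    if (run$fate[l] == "extant") {
      list(str = labels[l], t_node = run$t_death[l], t_top = t_top)
    } else {
      a <- descend(kk[1]); b <- descend(kk[2])
      str <- sprintf("(%s:%.10g,%s:%.10g)",
                     a$str, a$t_node - a$t_top, b$str, b$t_node - b$t_top)
      list(str = str, t_node = run$t_death[l], t_top = t_top)
    }
  }
  root <- descend(1L)
  tree <- ape::read.tree(text = paste0(root$str, ";"))
  depth <- ape::node.depth.edgelength(tree)
  t_root <- root$t_node
  attr(tree, "node_time") <- t_root + depth
  attr(tree, "t_root") <- t_root
  attr(tree, "n_extinct") <- n_extinct
  tree
}
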