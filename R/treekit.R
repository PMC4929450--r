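# Tree construction and topology comparison: neighbour-joining over AF
# distance matrices, non-trivial bipartition extraction, and the raw /
# normalized Robinson-Foulds distance used to score trees against a
# reference.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbour-joining (Studier-Keppler criterion, via
#' [ape::nj()]); on an additive matrix the generating topology and branch
#' lengths are recovered exactly. An all-zero matrix yields a star tree
#' with zero branch lengths.
#'
#' @param m Symmetric distance matrix with taxon dimnames and zero
#'   diagonal (as from [distance_matrix()]).
#' @param clamp_negative Set negative NJ branch lengths to zero
#'   (default `FALSE`, PHYLIP-compatible).
#' @return An unrooted [ape::phylo] tree.
#' @export
#' @examples
#' tr <- ape::rtree(6)
#' m <- cophenetic(tr)
#' rf_raw(neighbor_joining(m), tr)  # 0
neighbor_joining <- function(m, clamp_negative = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("neighbour-joining needs at least 3 taxa")
  if (anyNA(m) || any(!is.finite(m))) stop("distance matrix contains NaN/Inf")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 0)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(m))) stop("distance matrix must carry taxon names")
  if (all(m == 0)) {  # degenerate: star tree
    n <- nrow(m)
    tree <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                 edge.length = rep(0, n), tip.label = rownames(m),
                 Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "order") <- "cladewise"
    return(tree)
  }
  tree <- ape::nj(m)
  if (clamp_negative) tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# canonical split keys with the test-tree node that induces each split:
# key = sorted labels of the block containing the lexicographically
# smallest leaf, ";"-joined
split_table <- function(tree) {
  labels <- tree$tip.label
  n <- length(labels)
  pp <- ape::prop.part(tree)
  smallest <- order(labels)[1]  # index of lexicographically min leaf
  keys <- character(0); nodes <- integer(0)
  for (i in seq_along(pp)) {
    blk <- pp[[i]]
    if (length(blk) == n) next                     # root: trivial
    if (length(blk) < 2 || n - length(blk) < 2) next  # trivial split
    side <- if (smallest %in% blk) blk else setdiff(seq_len(n), blk)
    keys <- c(keys, paste(sort(labels[side]), collapse = ";"))
    nodes <- c(nodes, n + i)  # prop.part is ordered by internal node id
  }
  dup <- duplicated(keys)   # rooted storage: the two root-child edges
  list(keys = keys[!dup], nodes = nodes[!dup])
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition (split) per internal edge; blocks with fewer than two
#' leaves are trivial and excluded. A fully resolved unrooted tree of `N`
#' leaves has `N - 3` bipartitions.
#'
#' @param tree An [ape::phylo] tree.
#' @return Character vector of canonical split keys (the block containing
#'   the lexicographically smallest leaf, sorted and `";"`-joined), with
#'   the full blocks in attribute `blocks`.
#' @export
#' @examples
#' length(bipartitions(ape::rtree(30)))  # 27
bipartitions <- function(tree) {
  keys <- split_table(tree)$keys
  attr(keys, "blocks") <- strsplit(keys, ";", fixed = TRUE)
  keys
}

check_same_leaves <- function(t1, t2) {
  a <- sort(t1$tip.label); b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    only1 <- setdiff(a, b); only2 <- setdiff(b, a)
    stop("trees have different leaf sets",
         if (length(only1)) paste0("; only in tree 1: ",
                                   paste(only1, collapse = ", ")),
         if (length(only2)) paste0("; only in tree 2: ",
                                   paste(only2, collapse = ", ")))
  }
}

#' Raw Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees (symmetric difference of split sets). Multifurcating trees are
#' compared by their split sets directly.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_raw <- function(t1, t2) {
  check_same_leaves(t1, t2)
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Normalized Robinson-Foulds distance
#'
#' [rf_raw()] divided by the maximum possible distance between two unrooted
#' trees of `N` leaves, `2(N - 3)`: 0 means identical topologies, 1 means
#' no shared non-trivial bipartition between two fully resolved trees.
#'
#' @inheritParams rf_raw
#' @return Value in `[0, 1]`.
#' @export
rf_normalized <- function(t1, t2) {
  check_same_leaves(t1, t2)
  n <- length(t1$tip.label)
  if (n <= 3) stop("normalized RF undefined for N <= 3 leaves")
  rf_raw(t1, t2) / (2 * (n - 3))
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that keep
#' branch lengths to 10+ significant digits and internal node labels
#' (support values) verbatim; rooted input is unrooted on load by default.
#'
#' @param path File path; for `newick_read`, `text` may be given instead.
#' @param text Newick string (alternative to `path`).
#' @param unroot Unroot the tree on load (default `TRUE`).
#' @return `newick_read`: an [ape::phylo]; `newick_write`: `path`,
#'   invisibly.
#' @export
newick_read <- function(path = NULL, text = NULL, unroot = TRUE) {
  tree <- if (is.null(text)) ape::read.tree(path)
          else ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed Newick input")
  if (unroot && ape::is.rooted(tree) && length(tree$tip.label) > 2)
    tree <- ape::unroot(tree)
  tree
}

#' @rdname newick_read
#' @param tree An [ape::phylo] tree.
#' @export
newick_write <- function(tree, path) {
  writeLines(ape::write.tree(tree, digits = 12), path)
  invisible(path)
}
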