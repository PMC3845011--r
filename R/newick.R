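#' Read a rooted binary tree from a Newick string
#'
#' Branch lengths are required and interpreted in coalescent time units
#' (1 unit = 2Ne generations). Node times are defined as the maximum path
#' length to a descendant tip, so tips sit at time 0.
#'
#' @param text a Newick string describing one rooted binary tree with branch
#'   lengths.
#' @return An [ape::read.tree] `phylo` object, validated.
#' @export
read_newick <- function(text) {
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick string")
  if (inherits(phy, "multiPhylo")) stop("expected a single tree")
  validate_tree(phy)
  phy
}

#' Write a tree as a Newick string
#'
#' @param tree a `phylo` object.
#' @return A Newick string; `read_newick(write_newick(tree))` reproduces the
#'   topology exactly and node times to 1e-9.
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  ape::write.tree(tree, digits = 15)
}

validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length)) {
    stop("tree must have branch lengths on every edge")
  }
  if (any(phy$edge.length < 0)) stop("negative branch length")
  n <- ape::Ntip(phy)
  kids <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  if (any(kids[-seq_len(n)] != 2L)) stop("non-binary tree")
  invisible(phy)
}

#' Node times of a tree
#'
#' Time of a node is its maximum path length to a descendant tip; tips are at
#' time 0.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return Numeric vector over nodes `1..(Ntip + Nnode)` (ape numbering).
#' @export
node_times <- function(tree) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  tm <- numeric(m)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    c <- po$edge[e, 2]
    tm[p] <- max(tm[p], tm[c] + po$edge.length[e])
  }
  tm
}

#' Time to the most recent common ancestor
#'
#' @param tree a `phylo` object with branch lengths.
#' @return The root node time (coalescent units).
#' @export
tmrca <- function(tree) {
  tm <- node_times(tree)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  tm[root]
}
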