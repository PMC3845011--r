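#' Enumerate eligible bipartition clusterings of a tree
#'
#' Every internal branch (an edge whose child is an internal, non-root node)
#' cuts the tips into two groups: the descendants of the branch and the rest.
#' A bipartition is eligible when both sides contain at least
#' `ceiling(min_frac * n)` tips; the two-sided rule keeps the complementary
#' near-singleton splits out as well, which is the point of a minimum cluster
#' size.
#'
#' @param tree a rooted binary `phylo` object.
#' @param min_frac minimum fraction of tips required on each side of the
#'   split; must satisfy `0 <= min_frac < 0.5`.
#' @return A tibble with one row per eligible bipartition, ordered by the
#'   branch's child node id: `branch` (ape node id of the child), `size`
#'   (cluster tip count) and `tips` (list-column of tip indices).
#' @export
enumerate_eligible_bipartitions <- function(tree, min_frac = 0.05) {
  validate_tree(tree)
  if (min_frac < 0 || min_frac >= 0.5) stop("min_frac must be in [0, 0.5)")
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  tips <- vector("list", m)
  tips[seq_len(n)] <- as.list(seq_len(n))
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    c <- po$edge[e, 2]
    tips[[p]] <- c(tips[[p]], tips[[c]])
  }
  root <- setdiff(po$edge[, 1], po$edge[, 2])
  internal <- setdiff((n + 1L):m, root)
  internal <- sort(internal)
  thr <- ceiling(min_frac * n)
  sizes <- lengths(tips[internal])
  keep <- sizes >= thr & (n - sizes) >= thr
  tibble::tibble(
    branch = internal[keep],
    size = as.integer(sizes[keep]),
    tips = lapply(tips[internal[keep]], function(x) sort(as.integer(x)))
  )
}

#' Robinson-Foulds symmetric distance between rooted trees
#'
#' The size of the symmetric difference between the two trees' sets of
#' non-trivial clades (descendant tip-label sets of internal non-root
#' branches).
#'
#' @param t1,t2 rooted binary `phylo` objects over the same tip labels.
#' @return Integer distance; 0 for identical topologies.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different tip label sets")
  }
  k1 <- clade_keys(t1)
  k2 <- clade_keys(t2)
  sum(!(k1 %in% k2)) + sum(!(k2 %in% k1))
}

clade_keys <- function(tree) {
  bp <- enumerate_eligible_bipartitions(tree, min_frac = 0)
  vapply(bp$tips, function(ix) {
    paste(sort(tree$tip.label[ix]), collapse = "\r")
  }, character(1))
}
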