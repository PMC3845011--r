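# Internal flat-array tree representation used by the MCMC core and the fast
# coalescent/statistic paths.
#
# arr: list(n_tips, parent, child1, child2, time, tip_labels)
#   - node ids: tips 1..n, internal nodes n+1..2n-1 (root may be any internal)
#   - parent[root] = 0; child1/child2 = 0 for tips
#   - time: coalescent units, tips at 0, child strictly younger than parent

new_tree_arrays <- function(n_tips, parent, child1, child2, time, tip_labels) {
  list(
    n_tips = as.integer(n_tips),
    parent = as.integer(parent),
    child1 = as.integer(child1),
    child2 = as.integer(child2),
    time = as.numeric(time),
    tip_labels = tip_labels
  )
}

arrays_root <- function(arr) which(arr$parent == 0L)

phylo_to_arrays <- function(phy) {
  validate_tree(phy)
  n <- ape::Ntip(phy)
  m <- n + phy$Nnode
  parent <- integer(m)
  child1 <- integer(m)
  child2 <- integer(m)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]
    c <- phy$edge[e, 2]
    parent[c] <- p
    if (child1[p] == 0L) child1[p] <- c else child2[p] <- c
  }
  new_tree_arrays(n, parent, child1, child2, node_times(phy), phy$tip.label)
}

arrays_to_phylo <- function(arr) {
  n <- arr$n_tips
  m <- 2L * n - 1L
  root <- arrays_root(arr)
  # preorder DFS assigns ape-style internal ids (root = n+1) and cladewise edges
  newid <- integer(m)
  newid[seq_len(n)] <- seq_len(n)
  edge <- matrix(0L, nrow = m - 1L, ncol = 2L)
  elen <- numeric(m - 1L)
  next_int <- n + 1L
  erow <- 0L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v > n) {
      newid[v] <- next_int
      next_int <- next_int + 1L
    }
    for (ch in c(arr$child1[v], arr$child2[v])) {
      if (ch != 0L) {
        erow <- erow + 1L
        edge[erow, 1] <- v # remapped after DFS completes
        edge[erow, 2] <- ch
        stack <- c(stack, ch)
      }
    }
  }
  # DFS with a stack visits child2 before child1; that is still a valid
  # cladewise order. Remap ids and fill branch lengths.
  elen <- arr$time[edge[, 1]] - arr$time[edge[, 2]]
  edge[, 1] <- newid[edge[, 1]]
  edge[, 2] <- newid[edge[, 2]]
  labels <- arr$tip_labels
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  phy <- structure(
    list(edge = edge, edge.length = elen, tip.label = labels,
         Nnode = n - 1L),
    class = "phylo", order = "cladewise"
  )
  phy
}

# descendant tip counts (and case counts) per node, by postorder accumulation
arrays_desc_counts <- function(arr, weights = NULL) {
  n <- arr$n_tips
  m <- 2L * n - 1L
  size <- integer(m)
  size[seq_len(n)] <- 1L
  wsum <- NULL
  if (!is.null(weights)) {
    wsum <- numeric(m)
    wsum[seq_len(n)] <- weights
  }
  ord <- order(arr$time[(n + 1L):m]) + n # internal nodes, youngest first
  for (v in ord) {
    c1 <- arr$child1[v]
    c2 <- arr$child2[v]
    size[v] <- size[c1] + size[c2]
    if (!is.null(wsum)) wsum[v] <- wsum[c1] + wsum[c2]
  }
  list(size = size, wsum = wsum)
}
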