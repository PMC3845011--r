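#' Sample a tree from the neutral coalescent
#'
#' Standard Kingman coalescent: while `k` lineages remain, the next
#' coalescence waits an Exponential(k(k-1)/2) time (coalescent units, 1 unit =
#' 2Ne generations) and a uniformly chosen pair merges. The result is an
#' ultrametric rooted binary tree with tips at time 0.
#'
#' Uses R's global random number generator; call [set.seed()] for
#' reproducibility.
#'
#' @param n_tips number of tips, at least 2.
#' @param tip_labels optional tip labels (default `t1 ... tn`).
#' @return A `phylo` object.
#' @export
sample_coalescent_tree <- function(n_tips, tip_labels = NULL) {
  arrays_to_phylo(sample_coal_arrays(n_tips, tip_labels))
}

sample_coal_arrays <- function(n, tip_labels = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n_tips must be at least 2")
  m <- 2L * n - 1L
  parent <- integer(m)
  child1 <- integer(m)
  child2 <- integer(m)
  time <- numeric(m)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  k <- n
  while (k > 1L) {
    t <- t + rexp(1L, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    a <- active[pair[1]]
    b <- active[pair[2]]
    parent[a] <- nxt
    parent[b] <- nxt
    child1[nxt] <- a
    child2[nxt] <- b
    time[nxt] <- t
    active[pair[1]] <- nxt
    active <- active[-pair[2]]
    nxt <- nxt + 1L
    k <- k - 1L
  }
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  new_tree_arrays(n, parent, child1, child2, time, tip_labels)
}

#' Sample the prior null distribution of the association statistic
#'
#' Draws `m` trees from the neutral coalescent with the phenotype labels held
#' fixed to the tip indices (tips are exchangeable under the coalescent, so
#' the binding is immaterial) and computes the bipartition maximum-correlation
#' statistic on each. The resulting sample estimates the prior (unconditional)
#' distribution of the statistic, against which latent p-values are computed.
#'
#' @param n_tips number of tips (haplotypes).
#' @param phenotype 0/1 vector of length `n_tips` with both classes present.
#' @param m number of prior draws.
#' @param min_frac bipartition eligibility fraction (default 0.05).
#' @return An object of class `prior_sample` with fields `statistics` (length
#'   `m`, values in `[0,1]`), `m`, `n_tips`, `min_frac`, `phenotype`.
#' @export
sample_prior_statistics <- function(n_tips, phenotype, m, min_frac = 0.05) {
  n_tips <- as.integer(n_tips)
  m <- as.integer(m)
  if (m < 1L) stop("m must be at least 1")
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != n_tips) stop("phenotype length must equal n_tips")
  check_two_classes(phenotype)
  if (min_frac < 0 || min_frac >= 0.5) stop("min_frac must be in [0, 0.5)")
  thr <- ceiling(min_frac * n_tips)
  ncase_tot <- sum(phenotype)
  stats <- vapply(
    seq_len(m),
    function(i) coal_topology_max_stat(n_tips, phenotype, thr, ncase_tot),
    numeric(1)
  )
  structure(
    list(statistics = stats, m = m, n_tips = n_tips, min_frac = min_frac,
         phenotype = phenotype),
    class = "prior_sample"
  )
}

#' @export
print.prior_sample <- function(x, ...) {
  cat(sprintf(
    "<prior_sample> M = %d coalescent draws, n = %d tips, min_frac = %g\n",
    x$m, x$n_tips, x$min_frac
  ))
  print(summary(x$statistics))
  invisible(x)
}

# simulate one coalescent topology (times not needed for the statistic) and
# return the max |phi| over eligible bipartitions
coal_topology_max_stat <- function(n, phen, thr, ncase_tot) {
  size <- rep(1L, n)
  ncase <- phen
  den <- sqrt(as.numeric(ncase_tot) * (n - ncase_tot))
  best <- -Inf
  k <- n
  while (k > 2L) {
    pair <- sample.int(k, 2L)
    i <- pair[1]
    j <- pair[2]
    s <- size[i] + size[j]
    cc <- ncase[i] + ncase[j]
    size[i] <- s
    ncase[i] <- cc
    size <- size[-j]
    ncase <- ncase[-j]
    if (s >= thr && (n - s) >= thr) {
      # phi of the 2x2 table (cases/controls x in/out of cluster)
      num <- abs(cc * ((n - s) - (ncase_tot - cc)) - (s - cc) * (ncase_tot - cc))
      v <- num / (den * sqrt(as.numeric(s) * (n - s)))
      if (v > best) best <- v
    }
    k <- k - 1L
  }
  # the final merge forms the root, which is not an internal branch
  if (!is.finite(best)) {
    stop("no eligible bipartition in a prior tree; lower min_frac")
  }
  best
}
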