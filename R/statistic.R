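#' Absolute phi correlation between cluster membership and case status
#'
#' The absolute Pearson correlation of two binary vectors equals the phi
#' coefficient of their 2x2 table `(a,b;c,d)`:
#' `|ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param cluster_member 0/1 (or logical) membership vector.
#' @param phenotype 0/1 (or logical) case status vector of equal length.
#' @return Absolute correlation in `[0, 1]`.
#' @export
binary_correlation <- function(cluster_member, phenotype) {
  x <- as.integer(as.logical(cluster_member))
  y <- as.integer(as.logical(phenotype))
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(unique(x)) < 2L) stop("cluster membership is constant")
  check_two_classes(y)
  a <- sum(x == 1L & y == 1L)
  b <- sum(x == 1L & y == 0L)
  c <- sum(x == 0L & y == 1L)
  d <- sum(x == 0L & y == 0L)
  abs(a * d - b * c) /
    sqrt(as.numeric(a + b) * (c + d) * (a + c) * (b + d))
}

#' Bipartition maximum-correlation association statistic
#'
#' The tree-based association statistic: the maximum, over all eligible
#' bipartition clusterings of the tree (see
#' [enumerate_eligible_bipartitions()]), of the absolute correlation between
#' cluster membership and case status. Large values indicate that case
#' haplotypes cluster together in the genealogy.
#'
#' @param tree a rooted binary `phylo` object.
#' @param phenotype 0/1 case status per tip. If named, names are matched to
#'   `tree$tip.label`; otherwise the order of tips is used.
#' @param min_frac eligibility fraction (both sides of every counted split
#'   must contain at least `ceiling(min_frac * n)` tips).
#' @return The statistic, a value in `[0, 1]`.
#' @export
max_correlation_statistic <- function(tree, phenotype, min_frac = 0.05) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  phenotype <- bind_phenotype(phenotype, tree$tip.label)
  check_two_classes(phenotype)
  arr <- phylo_to_arrays(tree)
  v <- max_stat_arrays(arr, phenotype, min_frac)
  if (is.na(v)) stop("no eligible bipartition for this tree and min_frac")
  v
}

bind_phenotype <- function(phenotype, tip_labels) {
  y <- as.integer(phenotype)
  if (length(y) != length(tip_labels)) {
    stop("phenotype length does not match the number of tips")
  }
  if (!is.null(names(phenotype))) {
    idx <- match(tip_labels, names(phenotype))
    if (anyNA(idx)) stop("phenotype names do not cover all tip labels")
    y <- y[idx]
  }
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("phenotype must be 0/1")
  y
}

# fast path on the internal array representation; returns NA when no
# bipartition is eligible
max_stat_arrays <- function(arr, phenotype, min_frac) {
  n <- arr$n_tips
  thr <- ceiling(min_frac * n)
  cnt <- arrays_desc_counts(arr, weights = phenotype)
  root <- arrays_root(arr)
  internal <- setdiff((n + 1L):(2L * n - 1L), root)
  s <- cnt$size[internal]
  cc <- cnt$wsum[internal]
  keep <- s >= thr & (n - s) >= thr
  if (!any(keep)) return(NA_real_)
  s <- s[keep]
  cc <- cc[keep]
  ncase <- sum(phenotype)
  num <- abs(cc * ((n - s) - (ncase - cc)) - (s - cc) * (ncase - cc))
  den <- sqrt(as.numeric(s) * (n - s) * ncase * (n - ncase))
  max(num / den)
}
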