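# shared fixtures and independent oracles

# brute-force bipartition maximum: explicit cluster enumeration + stats::cor,
# independent of the production descendant-count path
brute_force_max_stat <- function(tree, phenotype, min_frac) {
  bp <- enumerate_eligible_bipartitions(tree, min_frac)
  if (!nrow(bp)) return(NA_real_)
  n <- ape::Ntip(tree)
  vals <- vapply(bp$tips, function(ix) {
    member <- as.integer(seq_len(n) %in% ix)
    abs(stats::cor(member, phenotype))
  }, numeric(1))
  max(vals)
}

balanced_phenotype <- function(n) {
  stopifnot(n >= 2)
  rep(c(1L, 0L), length.out = n)[sample.int(n)]
}

# small random panel with both phenotype classes
small_panel <- function(n = 8, L = 5) {
  alle <- matrix(rbinom(n * L, 1, 0.5), n, L)
  alle[1:2, 1] <- c(0L, 1L)
  hap_data(alle, seq_len(L) * 100, rep(c(0L, 1L), length.out = n))
}

# batch-means Monte Carlo standard error for a (possibly autocorrelated)
# chain of values
mcse_batch <- function(x, n_batch = 40) {
  nb <- min(n_batch, floor(length(x) / 2))
  len <- floor(length(x) / nb)
  bm <- colMeans(matrix(x[seq_len(nb * len)], nrow = len))
  stats::sd(bm) / sqrt(nb)
}

caterpillar6 <- function() {
  read_newick("(((((t1:1,t2:1):1,t3:2):1,t4:3):1,t5:4):1,t6:5);")
}
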