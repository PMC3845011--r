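prior_of <- function(stats) {
  structure(list(statistics = stats, m = length(stats), n_tips = NA,
                 min_frac = 0.05, phenotype = NULL),
            class = "prior_sample")
}

test_that("latent p-values use the inclusive tail fraction", {
  pr <- prior_of(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(latent_pvalue(0.25, pr), 0.5)
  expect_equal(latent_pvalue(0.5, pr), 0)
  expect_equal(latent_pvalue(0.05, pr), 1)
  expect_equal(latent_pvalue(0.1, pr), 1)    # inclusive at the minimum
  expect_equal(latent_pvalue(0.2, pr), 0.75) # ties count
  expect_equal(latent_pvalue(c(0.25, 0.35), pr), c(0.5, 0.25))
})

test_that("fuzzy p-value summaries are order statistics with zero replacement", {
  pr <- prior_of(seq(0.01, 1, by = 0.01))
  t_c <- c(0.5, 0.105, 0.75, 0.3, 0.9)
  fz <- fuzzy_pvalue(t_c, pr)
  expect_equal(fz$latent_p, latent_pvalue(t_c, pr))
  qs <- unname(stats::quantile(fz$latent_p, c(0.5, 0.25, 0.75, 0.9)))
  expect_equal(fz$summaries$median, qs[1])
  expect_equal(fz$summaries$q25, qs[2])
  expect_equal(fz$summaries$q75, qs[3])
  expect_equal(fz$summaries$q90, qs[4])
  expect_false(fz$zero_replaced_for_log)

  # every posterior statistic below the prior minimum: all latent p = 1
  fz1 <- fuzzy_pvalue(rep(0.001, 7), pr)
  expect_true(all(fz1$latent_p == 1))
  expect_equal(fz1$summaries$median, 1)

  # single tree: the median is that latent p
  fz2 <- fuzzy_pvalue(0.5, pr)
  expect_equal(fz2$summaries$median, fz2$latent_p)

  # zero summaries are replaced by 1/M on the log scale and flagged
  fz3 <- fuzzy_pvalue(rep(2, 5), pr)
  expect_equal(fz3$summaries$median, 0)
  expect_equal(fz3$summaries_log$median, 1 / pr$m)
  expect_true(fz3$zero_replaced_for_log)
  expect_equal(-log10(fz3$summaries_log$median), log10(pr$m))

  g <- glance(fz)
  expect_equal(g$n_trees, 5L)
  expect_equal(g$median, fz$summaries$median)
  expect_equal(nrow(tidy(fz)), 5L)
})

test_that("permutation companion reuses the sampled trees", {
  set.seed(51)
  trees <- replicate(20, sample_coalescent_tree(16), simplify = FALSE)
  phen <- stats::setNames(rep(c(1L, 0L), each = 8), trees[[1]]$tip.label)
  pr <- prior_of(runif(500))
  t_c <- vapply(trees, max_correlation_statistic, numeric(1),
                phenotype = phen, min_frac = 0.05)
  direct <- fuzzy_pvalue(t_c, pr)
  ident <- permutation_fuzzy(trees, phen, pr, perm = seq_len(16))
  expect_identical(ident$latent_p, direct$latent_p)

  set.seed(99)
  a <- permutation_fuzzy(trees, phen, pr)
  set.seed(99)
  b <- permutation_fuzzy(trees, phen, pr)
  expect_identical(a$latent_p, b$latent_p)
})

test_that("permuted labels show no association against coalescent trees", {
  set.seed(52)
  n <- 20
  trees <- replicate(30, sample_coalescent_tree(n), simplify = FALSE)
  phen <- stats::setNames(rep(c(1L, 0L), each = 10), trees[[1]]$tip.label)
  pr <- sample_prior_statistics(n, unname(phen), 400)
  hits <- 0
  for (r in 1:100) {
    fz <- permutation_fuzzy(trees, phen, pr)
    if (fz$summaries$median > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("Fisher exact per SNP matches hypergeometric enumeration", {
  alle <- cbind(rep(c(1L, 0L), each = 10),  # perfect separation
                rep(c(1L, 0L), 10),         # balanced (table 5,5;5,5)
                rep(1L, 20))                # monomorphic
  d <- hap_data(alle, c(100, 200, 300), rep(c(1L, 0L), each = 10))
  f <- fisher_exact_per_snp(d)
  expect_equal(f$p[1], 2 / choose(20, 10))
  expect_equal(f$p[2], 1)
  expect_equal(f$p[3], 1)
  expect_identical(f$monomorphic, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(f), 3L)

  # swapping case/control labels transposes every table: p unchanged
  d2 <- d
  d2$phenotype <- 1L - d2$phenotype
  expect_equal(fisher_exact_per_snp(d2)$p, f$p)
})

test_that("Bonferroni thresholds divide the level by the test count", {
  expect_equal(bonferroni_threshold(0.05, 100), 5e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 103), 0.05 / 103)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})
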