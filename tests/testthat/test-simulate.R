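test_that("scenario validation enforces its invariants", {
  expect_error(synth_scenario(causal_freq_range = c(0, 0.5)), "inside")
  expect_error(synth_scenario(penetrance = c(0.9, 0.1)), "g1 >= g0")
  sc <- synth_scenario()
  expect_s3_class(sc, "synth_scenario")
  expect_equal(sc$rho_true, 4e-4)
})

test_that("the generator is deterministic given its seed", {
  s1 <- simulate_case_control(synth_scenario(seed = 101))
  s2 <- simulate_case_control(synth_scenario(seed = 101))
  expect_identical(s1$data$alleles, s2$data$alleles)
  expect_identical(s1$data$phenotype, s2$data$phenotype)
  expect_identical(s1$causal_bp, s2$causal_bp)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
})

test_that("fully penetrant carriers make the true tree perfectly associated", {
  sim <- simulate_case_control(synth_scenario(
    penetrance = c(0, 1), causal_freq_range = c(0.49, 0.51), seed = 103
  ))
  expect_setequal(which(sim$data$phenotype == 1L), sim$carriers)
  stat <- max_correlation_statistic(
    sim$tree, stats::setNames(sim$data$phenotype, sim$data$haplotype_ids)
  )
  expect_equal(stat, 1.0)
})

test_that("an unattainable causal frequency range errors after redraws", {
  # n = 10: descendant frequencies are multiples of 0.1, none in (0.42, 0.48)
  expect_error(
    simulate_case_control(synth_scenario(
      n_case = 5, n_control = 5, causal_freq_range = c(0.42, 0.48),
      seed = 104
    )),
    "1000 tree redraws"
  )
})

test_that("markers pushed to unlinked distances are independent of phenotype", {
  # rho_true = 10 makes every off-causal marker land on an independent tree
  set.seed(105)
  ps <- c()
  for (r in 1:200) {
    sim <- simulate_case_control(synth_scenario(
      n_snps = 10, rho_true = 10, seed = 7000 + r
    ))
    f <- fisher_exact_per_snp(sim$data)
    keep <- abs(sim$data$positions - sim$causal_bp) > 0 & !f$monomorphic
    ps <- c(ps, f$p[keep])
  }
  # exact-test validity: discrete conditional p-values are conservative,
  # so tail probabilities must not exceed their nominal level (+ MC slack)
  for (a in c(0.01, 0.05, 0.1, 0.2)) {
    slack <- 3 * sqrt(a * (1 - a) / length(ps))
    expect_lte(mean(ps <= a), a + slack)
  }
  # and indistinguishable from an explicit label-permutation null
  set.seed(106)
  ps_perm <- c()
  for (r in 1:200) {
    sim <- simulate_case_control(synth_scenario(
      n_snps = 10, rho_true = 10, seed = 8000 + r
    ))
    d <- sim$data
    d$phenotype <- d$phenotype[sample.int(length(d$phenotype))]
    f <- fisher_exact_per_snp(d)
    keep <- abs(sim$data$positions - sim$causal_bp) > 0 & !f$monomorphic
    ps_perm <- c(ps_perm, f$p[keep])
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, ps_perm))$p.value, 0.01)
})

test_that("allelic correlation with the causal variant decays with distance", {
  set.seed(107)
  dist_all <- c()
  cor_all <- c()
  for (r in 1:200) {
    sim <- simulate_case_control(synth_scenario(seed = 9000 + r))
    carrier <- as.integer(seq_len(50) %in% sim$carriers)
    for (j in seq_len(ncol(sim$data$alleles))) {
      a <- sim$data$alleles[, j]
      if (length(unique(a)) < 2L) next
      dist_all <- c(dist_all, abs(sim$data$positions[j] - sim$causal_bp))
      cor_all <- c(cor_all, abs(stats::cor(a, carrier)))
    }
  }
  bins <- cut(dist_all, c(-1, 400, 800, 1600, Inf))
  means <- tapply(cor_all, bins, mean)
  expect_false(anyNA(means))
  expect_true(all(diff(means) <= 0))
})
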