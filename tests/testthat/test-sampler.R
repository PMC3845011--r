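test_that("mh_acceptance implements the capped Metropolis-Hastings ratio", {
  expect_equal(mh_acceptance(-5, -5, -1, -1), 1)
  expect_equal(mh_acceptance(log(2) - 5, -5), 1)     # ratio 2, symmetric
  expect_equal(mh_acceptance(log(0.5) - 5, -5), 0.5)
  expect_equal(mh_acceptance(-Inf, -5), 0)
  expect_error(mh_acceptance(-5, -Inf), "finite")
})

test_that("sampler configuration is validated up front", {
  expect_error(sampler_config(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(sampler_config(proposal_probs = c(0.5, 0.5, 0, 0, 0.1)),
               "sum to 1")
  expect_error(sampler_config(theta_init = 20), "prior support")
  expect_error(sampler_config(thin = 0), "thin")
})

test_that("proposal kernels change exactly the targeted component", {
  set.seed(61)
  d <- small_panel(n = 10, L = 6)
  st <- initial_state(d, 1:6)

  pt <- propose(st, "theta")
  expect_identical(pt$state$tree, st$tree)
  expect_identical(pt$state$hap, st$hap)
  expect_equal(pt$state$rho, st$rho)
  expect_false(pt$state$theta == st$theta)
  # log-scale random walk Jacobian: lq_rev - lq_fwd = log(theta'/theta)
  expect_equal(pt$log_q_reverse - pt$log_q_forward,
               log(pt$state$theta / st$theta))

  pr <- propose(st, "rho")
  expect_equal(pr$log_q_reverse - pr$log_q_forward,
               log(pr$state$rho / st$rho))
  expect_equal(pr$state$theta, st$theta)

  pf <- propose(st, "internal_haplotype")
  expect_equal(pf$log_q_forward, pf$log_q_reverse)
  expect_equal(sum(pf$state$hap != st$hap), 1L)
  changed <- which(pf$state$hap != st$hap, arr.ind = TRUE)
  expect_gt(changed[1], 10) # only internal nodes are touched
  expect_identical(pf$state$tree, st$tree)
})

test_that("topology kernels preserve tree validity", {
  set.seed(62)
  d <- small_panel(n = 12, L = 4)
  st <- initial_state(d, 1:4)
  check_arr <- function(arr) {
    n <- arr$n_tips
    m <- 2L * n - 1L
    expect_equal(sum(arr$parent == 0L), 1L)           # one root
    expect_true(all(arr$time[seq_len(n)] == 0))       # tips at 0
    kids <- arr$parent[arr$parent != 0L]
    expect_true(all(tabulate(kids, m)[(n + 1):m] %in% c(0L, 2L)))
    nonroot <- which(arr$parent != 0L)
    expect_true(all(arr$time[arr$parent[nonroot]] > arr$time[nonroot]))
  }
  for (i in 1:100) {
    kind <- sample(c("topology_local", "topology_spr"), 1)
    out <- propose(st, kind)
    check_arr(out$state$tree)
    expect_true(is.finite(out$log_q_forward))
    expect_true(is.finite(out$log_q_reverse))
    st <- out$state
  }
})

test_that("a 2-tip local move only resamples the coalescence time", {
  set.seed(63)
  hap2 <- matrix(c(0L, 1L, 0L), 3, 1)
  res <- treeassoc:::cpp_propose(
    c(2L, 2L, -1L), c(-1L, -1L, 0L), c(-1L, -1L, 1L), c(0, 0, 0.4), hap2,
    0.1, 0.1, 4L, 0.5, 0.5
  )
  expect_equal(res$parent, c(2L, 2L, -1L))  # topology unchanged
  expect_false(res$time[3] == 0.4)          # root time redrawn
  expect_true(res$time[3] > 0)
})

test_that("log_target reduces to the prior terms on a zero-SNP window", {
  set.seed(64)
  d <- small_panel(n = 9, L = 3)
  cfg <- sampler_config()
  st <- initial_state(d, integer(0), cfg)
  lt <- log_target(st, d, 500, integer(0), cfg)
  itimes <- sort(st$tree$time[st$tree$time > 0])
  k <- seq(9, 2)
  coal <- -sum(k * (k - 1) / 2 * diff(c(0, itimes)))
  manual <- coal - log(10 - 1e-4) +
    stats::dgamma(st$rho, 1, scale = 0.1, log = TRUE)
  expect_equal(lt, manual)

  # theta outside the uniform prior support has zero density
  st$theta <- 5e-5
  expect_equal(log_target(st, d, 500, integer(0), cfg), -Inf)
})

test_that("the emission likelihood matches a hand-coded two-state chain", {
  # 2-tip tree, one SNP: discordant tips below a shared ancestor
  t <- 0.7
  theta <- 0.3
  rho <- 0.002
  dd <- 50
  f <- 0.5
  for (hroot in 0:1) {
    hap <- matrix(c(1L, 0L, hroot), 3, 1)
    val <- treeassoc:::cpp_log_target(
      c(2L, 2L, -1L), c(-1L, -1L, 0L), c(-1L, -1L, 1L), c(0, 0, t), hap,
      f, dd, theta, rho, c(1e-4, 10), c(1, 0.1)
    )
    em <- exp(-theta * t)
    # child 1 allele = 1, child 2 allele = 0, root allele = hroot
    p1 <- if (hroot == 1) (1 + em) / 2 else (1 - em) / 2
    p0 <- if (hroot == 0) (1 + em) / 2 else (1 - em) / 2
    chain <- p1 * p0 * 0.5
    freqc <- 0.5^3
    w <- exp(-rho / 2 * dd * (2 * t))
    manual <- -t - log(10 - 1e-4) +
      stats::dgamma(rho, 1, scale = 0.1, log = TRUE) +
      log(w * chain + (1 - w) * freqc)
    expect_equal(val, manual)
  }
})

test_that("run_sampler retains the documented number of reproducible samples", {
  d <- small_panel(n = 8, L = 5)
  cfg <- sampler_config(n_iterations = 1000, burn_in = 500, thin = 50,
                        seed = 65)
  fr <- run_sampler(d, 250, 1:5, cfg)
  expect_equal(fr$n_retained, 10L)
  expect_length(fr$theta, 10L)
  expect_length(fr$tmrca, 10L)
  fr2 <- run_sampler(d, 250, 1:5, cfg)
  expect_identical(fr$theta, fr2$theta)
  expect_identical(fr$rho, fr2$rho)
  expect_identical(fr$parent, fr2$parent)
  expect_error(run_sampler(d, 250, 1:99, cfg), "out of range")
})

test_that("retained trees are valid and all kernels accept on informative data", {
  set.seed(66)
  sim <- simulate_case_control(synth_scenario(seed = 660))
  cfg <- sampler_config(n_iterations = 20000, burn_in = 5000, thin = 100,
                        seed = 67)
  fr <- run_sampler(sim$data, sim$causal_bp, 1:20, cfg)
  expect_true(all(fr$acceptance$rate > 0 & fr$acceptance$rate < 1))
  trees <- sampled_trees(fr)
  for (tr in trees[c(1, 50, 150)]) {
    expect_silent(treeassoc:::validate_tree(tr))
    expect_equal(ape::Ntip(tr), 50L)
  }
  # mixing diagnostic: RF distances recorded against the previous sample
  expect_true(all(is.na(fr$rf_prev[1]) | fr$rf_prev[1] >= 0))
  expect_true(all(fr$rf_prev[-1] >= 0))
  expect_equal(summarize_rates(fr)$mean_rho, mean(fr$rho))
})

test_that("the incremental log target matches full recomputation after a run", {
  set.seed(68)
  sim <- simulate_case_control(synth_scenario(n_case = 10, n_control = 10,
                                              n_snps = 8, seed = 680))
  st <- initial_state(sim$data, 1:8)
  tc <- treeassoc:::arr_to_cpp(st$tree)
  geom <- treeassoc:::window_geometry(sim$data, sim$causal_bp, 1:8)
  res <- treeassoc:::cpp_run_chain(
    tc$parent, tc$child1, tc$child2, tc$time, st$hap, geom$freq, geom$dist,
    0.1, 4e-4, c(1e-4, 10), c(1, 0.1), c(0.1, 0.1, 0.3, 0.25, 0.25),
    0.5, 0.5, 30000L, 1000L, 100L
  )
  expect_equal(res$incremental_total, res$final_total, tolerance = 1e-8)
  fs <- res$final_state
  direct <- treeassoc:::cpp_log_target(
    fs$parent, fs$child1, fs$child2, fs$time, fs$hap, geom$freq, geom$dist,
    fs$theta, fs$rho, c(1e-4, 10), c(1, 0.1)
  )
  expect_equal(direct, res$final_total, tolerance = 1e-10)
})

test_that("3-tip chain matches exhaustive integration of the target", {
  # fixed rates; only haplotype and topology kernels move
  f <- 1 / 3
  d <- 300
  theta <- 0.5
  rho <- 1e-3
  a <- c(1L, 0L, 0L)
  pmut <- function(same, t) 0.5 * (1 + ifelse(same, 1, -1) * exp(-theta * t))
  marg <- function(pair) {
    i <- pair[1]; j <- pair[2]; k <- setdiff(1:3, pair)
    x <- seq(0.005, 7, by = 0.01)
    y <- seq(0.005, 11, by = 0.01)
    X <- rep(x, times = length(y))
    Y <- rep(y, each = length(x))
    tv <- X
    tr <- X + Y
    w <- exp(-rho / 2 * d * (tv + 2 * tr))
    tot <- 0
    for (hv in 0:1) for (hr in 0:1) {
      chain <- pmut(a[i] == hv, tv) * pmut(a[j] == hv, tv) *
        pmut(hv == hr, tr - tv) * pmut(a[k] == hr, tr) *
        (f^hr * (1 - f)^(1 - hr))
      ones <- a[i] + a[j] + a[k] + hv + hr
      freqc <- f^ones * (1 - f)^(5 - ones)
      tot <- tot + sum(exp(-3 * tv - Y) * (w * chain + (1 - w) * freqc))
    }
    tot
  }
  ints <- c(marg(c(1, 2)), marg(c(1, 3)), marg(c(2, 3)))
  oracle <- ints / sum(ints)

  set.seed(31)
  hap <- matrix(c(a, 0L, 0L), 5, 1)
  res <- treeassoc:::cpp_run_chain(
    c(3L, 3L, 4L, 4L, -1L), c(-1L, -1L, -1L, 0L, 2L),
    c(-1L, -1L, -1L, 1L, 3L), c(0, 0, 0, 0.3, 0.8), hap, f, d, theta, rho,
    c(1e-4, 10), c(1, 0.1), c(0, 0, 0.4, 0.3, 0.3), 0.5, 0.5,
    600000L, 100000L, 20L
  )
  lab <- apply(res$parent, 2, function(p) {
    intn <- which(p >= 0)
    v <- intn[intn > 3]
    paste(sort(which(p[1:3] == (v - 1))), collapse = "")
  })
  for (tpl in c("12", "13", "23")) {
    ind <- as.numeric(lab == tpl)
    se <- mcse_batch(ind, 50)
    i <- match(tpl, c("12", "13", "23"))
    expect_lt(abs(mean(ind) - oracle[i]), 3 * se + 0.004)
  }
})
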