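#' Configuration for the focal-point MCMC sampler
#'
#' Defaults follow the method's standard analysis settings: a uniform
#' (0.0001, 10) prior on the mutation rate theta initialized at 0.1, a
#' gamma(shape 1, scale 0.1) prior on the recombination rate rho initialized
#' at 0.0004 (1 cM/Mb at Ne = 10,000), and five proposal kernels chosen at
#' each iteration with the given probabilities: mutation-rate and
#' recombination-rate log-scale random walks, a single internal-node allele
#' flip, a local (nearest-neighbour) topology rearrangement, and
#' subtree-prune-regraft. The default chain length (200,000 iterations,
#' 100,000 burn-in, thin 100) is a desk-scale setting; production analyses of
#' large panels use much longer chains.
#'
#' @param n_iterations total MCMC iterations.
#' @param burn_in iterations discarded before retention; `< n_iterations`.
#' @param thin retain every `thin`-th post-burn-in state.
#' @param proposal_probs probabilities of the five kernels, in the order
#'   theta, rho, internal_haplotype, topology_local, topology_spr; must sum
#'   to 1.
#' @param theta_prior `c(lo, hi)` of the uniform prior on theta.
#' @param rho_prior `c(shape, scale)` of the gamma prior on rho.
#' @param theta_init,rho_init initial rates (inside prior support).
#' @param delta_theta,delta_rho half-widths of the log-scale random walks.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_iterations = 200000, burn_in = 100000,
                           thin = 100,
                           proposal_probs = c(0.1, 0.1, 0.3, 0.25, 0.25),
                           theta_prior = c(1e-4, 10),
                           rho_prior = c(shape = 1, scale = 0.1),
                           theta_init = 0.1, rho_init = 4e-4,
                           delta_theta = 0.5, delta_rho = 0.5, seed = NULL) {
  stopifnot(n_iterations >= 1, burn_in >= 0, thin >= 1)
  if (burn_in >= n_iterations) stop("burn_in must be smaller than n_iterations")
  if (length(proposal_probs) != 5L || any(proposal_probs < 0)) {
    stop("proposal_probs must be 5 nonnegative values")
  }
  if (abs(sum(proposal_probs) - 1) > 1e-12) {
    stop("proposal_probs must sum to 1")
  }
  stopifnot(length(theta_prior) == 2L, theta_prior[1] > 0,
            theta_prior[2] > theta_prior[1],
            length(rho_prior) == 2L, all(rho_prior > 0))
  if (theta_init < theta_prior[1] || theta_init > theta_prior[2]) {
    stop("theta_init outside prior support")
  }
  if (rho_init <= 0) stop("rho_init must be positive")
  structure(
    list(n_iterations = as.integer(n_iterations),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         proposal_probs = as.numeric(proposal_probs),
         theta_prior = as.numeric(theta_prior),
         rho_prior = as.numeric(rho_prior),
         theta_init = theta_init, rho_init = rho_init,
         delta_theta = delta_theta, delta_rho = delta_rho, seed = seed),
    class = "sampler_config"
  )
}

proposal_kinds <- c("theta", "rho", "internal_haplotype", "topology_local",
                    "topology_spr")

# ---- augmented state -------------------------------------------------------

new_aug_state <- function(tree_arr, hap, theta, rho) {
  structure(list(tree = tree_arr, hap = hap, theta = theta, rho = rho),
            class = "aug_state")
}

#' Deterministic initial augmented state for a focal-point run
#'
#' The initial tree is UPGMA on Hamming distances between the window
#' haplotypes, with node times rescaled so the root sits at the coalescent
#' expectation `2(1 - 1/n)`; internal-node haplotypes start at the majority
#' allele of their descendant tips. With an empty window (a prior-only run)
#' the initial tree is drawn from the coalescent prior instead.
#'
#' @param data a [hap_data] panel.
#' @param window integer indices of the SNPs in the focal window (may be
#'   empty).
#' @param config a [sampler_config] (supplies the initial rates).
#' @return An object of class `aug_state`.
#' @export
initial_state <- function(data, window, config = sampler_config()) {
  stopifnot(inherits(data, "hap_data"))
  n <- nrow(data$alleles)
  window <- as.integer(window)
  if (length(window) && (min(window) < 1 || max(window) > ncol(data$alleles))) {
    stop("window indices out of range")
  }
  if (length(window)) {
    arr <- upgma_arrays(data$alleles[, window, drop = FALSE],
                        data$haplotype_ids)
  } else {
    arr <- sample_coal_arrays(n, data$haplotype_ids)
  }
  hap <- init_internal_hap(arr, data$alleles[, window, drop = FALSE])
  new_aug_state(arr, hap, config$theta_init, config$rho_init)
}

upgma_arrays <- function(alleles_w, tip_labels) {
  n <- nrow(alleles_w)
  hc <- stats::hclust(stats::dist(alleles_w, method = "manhattan"),
                      method = "average")
  tgt <- 2 * (1 - 1 / n)
  h <- hc$height / 2
  if (max(h) <= 0) h <- seq_len(n - 1L) / (n - 1)
  h <- h * (tgt / max(h))
  for (i in seq_along(h)) { # strictly increasing merge times
    lo <- if (i == 1L) 0 else h[i - 1L]
    if (h[i] <= lo) h[i] <- lo + tgt * 1e-6
  }
  h <- h * (tgt / max(h))
  m <- 2L * n - 1L
  parent <- integer(m)
  child1 <- integer(m)
  child2 <- integer(m)
  time <- numeric(m)
  for (i in seq_len(n - 1L)) {
    node <- n + i
    kids <- hc$merge[i, ]
    kids <- ifelse(kids < 0, -kids, n + kids)
    child1[node] <- kids[1]
    child2[node] <- kids[2]
    parent[kids] <- node
    time[node] <- h[i]
  }
  new_tree_arrays(n, parent, child1, child2, time, tip_labels)
}

init_internal_hap <- function(arr, alleles_w) {
  n <- arr$n_tips
  m <- 2L * n - 1L
  L <- ncol(alleles_w)
  hap <- matrix(0L, m, L)
  if (L == 0L) return(hap)
  hap[seq_len(n), ] <- alleles_w
  sizes <- arrays_desc_counts(arr)$size
  for (j in seq_len(L)) {
    ones <- arrays_desc_counts(arr, weights = alleles_w[, j])$wsum
    hap[(n + 1L):m, j] <- as.integer(ones[(n + 1L):m] / sizes[(n + 1L):m] >= 0.5)
  }
  hap
}

arr_to_cpp <- function(arr) {
  list(parent = ifelse(arr$parent == 0L, -1L, arr$parent - 1L),
       child1 = ifelse(arr$child1 == 0L, -1L, arr$child1 - 1L),
       child2 = ifelse(arr$child2 == 0L, -1L, arr$child2 - 1L),
       time = arr$time)
}

cpp_to_arr <- function(st, n_tips, tip_labels) {
  new_tree_arrays(
    n_tips,
    ifelse(st$parent < 0L, 0L, st$parent + 1L),
    ifelse(st$child1 < 0L, 0L, st$child1 + 1L),
    ifelse(st$child2 < 0L, 0L, st$child2 + 1L),
    st$time, tip_labels
  )
}

window_geometry <- function(data, focal_bp, window) {
  window <- as.integer(window)
  list(
    freq = if (length(window)) colMeans(data$alleles[, window, drop = FALSE])
           else numeric(0),
    dist = if (length(window)) abs(data$positions[window] - focal_bp)
           else numeric(0)
  )
}

#' Unnormalized log posterior density of an augmented state
#'
#' The sum of the coalescent log prior of the tree (node times), the log
#' prior densities of theta and rho, and the emission log-likelihood of the
#' tip and internal haplotypes: each marker is linked to the focal genealogy
#' with probability `exp(-(rho/2) * d * T)` (`d` its bp distance from the
#' focal point, `T` the tree's total branch length), in which case its allele
#' column follows a symmetric two-state mutation chain with per-branch flip
#' probability `(1 - exp(-theta t))/2` and a root allele drawn from the
#' marker's sample frequency; otherwise the whole column is iid from the
#' sample frequency. Returns `-Inf` when theta or rho leaves the prior
#' support.
#'
#' @param state an `aug_state`.
#' @param data a [hap_data] whose rows are bound to the tree tips.
#' @param focal_bp focal position (bp).
#' @param window integer indices of window SNPs (may be empty, in which case
#'   the likelihood term is exactly zero).
#' @param config a [sampler_config] (supplies the priors).
#' @return Unnormalized log density.
#' @export
log_target <- function(state, data, focal_bp, window,
                       config = sampler_config()) {
  stopifnot(inherits(state, "aug_state"), inherits(data, "hap_data"))
  if (!identical(state$tree$tip_labels, data$haplotype_ids)) {
    stop("state tips are not bound to the data haplotypes")
  }
  geom <- window_geometry(data, focal_bp, window)
  if (ncol(state$hap) != length(geom$freq)) {
    stop("state haplotypes do not match the window width")
  }
  tc <- arr_to_cpp(state$tree)
  cpp_log_target(tc$parent, tc$child1, tc$child2, tc$time, state$hap,
                 geom$freq, geom$dist, state$theta, state$rho,
                 config$theta_prior, config$rho_prior)
}

#' Metropolis-Hastings acceptance probability
#'
#' `min(1, exp(log_target_new - log_target_old + log_q_reverse -
#' log_q_forward))`; a `-Inf` new target gives 0.
#'
#' @param log_target_new,log_target_old unnormalized log target densities.
#' @param log_q_reverse,log_q_forward log proposal densities of the reverse
#'   and forward moves.
#' @return Acceptance probability in `[0, 1]`.
#' @export
mh_acceptance <- function(log_target_new, log_target_old,
                          log_q_reverse = 0, log_q_forward = 0) {
  if (!is.finite(log_target_old)) stop("old log target must be finite")
  la <- log_target_new - log_target_old + log_q_reverse - log_q_forward
  if (is.nan(la)) return(0)
  min(1, exp(la))
}

#' Draw one proposal from a sampler kernel
#'
#' Applies one of the five kernels to the state and returns the proposed
#' state together with the forward and reverse log proposal densities needed
#' for the Metropolis-Hastings ratio. Exactly the targeted component changes:
#' rate moves are log-scale random-walk multipliers, the haplotype move flips
#' one internal-node allele, and the two topology moves are a
#' nearest-neighbour swap and subtree-prune-regraft, each redrawing the
#' affected node time in its valid interval.
#'
#' @param state an `aug_state`.
#' @param kind one of `"theta"`, `"rho"`, `"internal_haplotype"`,
#'   `"topology_local"`, `"topology_spr"`.
#' @param config a [sampler_config] (supplies the random-walk widths).
#' @return A list with `state` (the proposed `aug_state`), `log_q_forward`
#'   and `log_q_reverse`.
#' @export
propose <- function(state, kind = proposal_kinds, config = sampler_config()) {
  stopifnot(inherits(state, "aug_state"))
  kind <- match.arg(kind)
  tc <- arr_to_cpp(state$tree)
  out <- cpp_propose(tc$parent, tc$child1, tc$child2, tc$time, state$hap,
                     state$theta, state$rho, match(kind, proposal_kinds),
                     config$delta_theta, config$delta_rho)
  hap <- out$hap
  dimnames(hap) <- NULL
  new_state <- new_aug_state(
    cpp_to_arr(out, state$tree$n_tips, state$tree$tip_labels),
    hap, out$theta, out$rho
  )
  list(state = new_state, log_q_forward = out$log_q_forward,
       log_q_reverse = out$log_q_reverse)
}

#' Run the focal-point Metropolis-Hastings sampler
#'
#' Samples the augmented state (tree, internal haplotypes, theta, rho) at
#' `focal_bp` conditional on the window haplotypes, retaining every
#' `thin`-th post-burn-in state. An empty window runs the chain against the
#' prior alone (useful as a correctness diagnostic: retained theta, rho and
#' TMRCA must then match their prior distributions); in that case the
#' internal-haplotype kernel is disabled and its probability redistributed.
#'
#' @param data a [hap_data] panel.
#' @param focal_bp focal position in bp.
#' @param window integer indices of the window SNPs (see [select_window()]).
#' @param config a [sampler_config].
#' @return An object of class `focal_result`: retained `theta`, `rho`,
#'   `tmrca` vectors, retained tree arrays, per-kind acceptance rates, and
#'   per-sample Robinson-Foulds distances to the previous retained tree.
#' @export
run_sampler <- function(data, focal_bp, window, config = sampler_config()) {
  stopifnot(inherits(data, "hap_data"), inherits(config, "sampler_config"))
  window <- as.integer(window)
  if (length(window) && (min(window) < 1 || max(window) > ncol(data$alleles))) {
    stop("window indices out of range")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(data$alleles)
  probs <- config$proposal_probs
  if (length(window) == 0L) {
    probs[3] <- 0
    probs <- probs / sum(probs)
  }
  state <- initial_state(data, window, config)
  geom <- window_geometry(data, focal_bp, window)
  tc <- arr_to_cpp(state$tree)
  res <- cpp_run_chain(tc$parent, tc$child1, tc$child2, tc$time, state$hap,
                       geom$freq, geom$dist, config$theta_init,
                       config$rho_init, config$theta_prior, config$rho_prior,
                       probs, config$delta_theta, config$delta_rho,
                       config$n_iterations, config$burn_in, config$thin)
  if (abs(res$final_total - res$incremental_total) > 1e-6 *
        max(1, abs(res$final_total))) {
    warning("incremental log-target drifted from the full recomputation")
  }
  parent1 <- res$parent + 1L # 1-based; root becomes 0
  parent1[res$parent < 0L] <- 0L
  keys <- apply_clade_keys(parent1, n)
  nret <- length(res$theta)
  rf_prev <- rep(NA_real_, nret)
  if (nret > 1L) {
    for (i in 2:nret) {
      rf_prev[i] <- length(setdiff(keys[[i - 1L]], keys[[i]])) +
        length(setdiff(keys[[i]], keys[[i - 1L]]))
    }
  }
  structure(
    list(
      focal_bp = focal_bp, window = window,
      theta = res$theta, rho = res$rho, tmrca = res$tmrca,
      parent = parent1, time = res$time,
      tip_labels = data$haplotype_ids,
      rf_prev = rf_prev,
      acceptance = tibble::tibble(
        kind = proposal_kinds,
        prob = probs,
        attempts = as.integer(res$attempts),
        accepts = as.integer(res$accepts),
        rate = ifelse(res$attempts > 0, res$accepts / res$attempts, NA_real_)
      ),
      config = config, n_retained = nret
    ),
    class = "focal_result"
  )
}

# clade keys (collapsed descendant tip-index strings) per retained sample
apply_clade_keys <- function(parent_mat, n) {
  lapply(seq_len(ncol(parent_mat)), function(s) {
    clades_from_parent(parent_mat[, s], n)
  })
}

clades_from_parent <- function(parent1, n) {
  m <- 2L * n - 1L
  root <- which(parent1 == 0L)
  members <- vector("list", m)
  members[seq_len(n)] <- as.list(seq_len(n))
  # accumulate tips upward; process nodes in an order where children precede
  # parents by repeatedly pushing tip sets along parent pointers
  for (tip in seq_len(n)) {
    v <- parent1[tip]
    while (v != 0L) {
      members[[v]] <- c(members[[v]], tip)
      v <- parent1[v]
    }
  }
  internal <- setdiff((n + 1L):m, root)
  vapply(internal, function(v) paste(sort(members[[v]]), collapse = ","),
         character(1))
}

#' Extract the retained trees of a focal-point run
#'
#' @param result a `focal_result`.
#' @return A list of `phylo` objects, one per retained sample.
#' @export
sampled_trees <- function(result) {
  stopifnot(inherits(result, "focal_result"))
  n <- (nrow(result$parent) + 1L) / 2L
  lapply(seq_len(result$n_retained), function(s) {
    arrays_to_phylo(parent_to_arrays(result$parent[, s], result$time[, s], n,
                                     result$tip_labels))
  })
}

parent_to_arrays <- function(parent1, time, n, tip_labels) {
  m <- 2L * n - 1L
  child1 <- integer(m)
  child2 <- integer(m)
  for (v in seq_len(m)) {
    p <- parent1[v]
    if (p != 0L) {
      if (child1[p] == 0L) child1[p] <- v else child2[p] <- v
    }
  }
  new_tree_arrays(n, parent1, child1, child2, time, tip_labels)
}

#' Posterior mean rates of a focal-point run
#'
#' @param result a `focal_result` with at least one retained sample.
#' @return A list with `mean_rho` and `mean_theta` (arithmetic means over the
#'   retained samples).
#' @export
summarize_rates <- function(result) {
  stopifnot(inherits(result, "focal_result"))
  if (result$n_retained < 1L) stop("no retained samples")
  list(mean_rho = mean(result$rho), mean_theta = mean(result$theta))
}

#' @export
print.focal_result <- function(x, ...) {
  cat(sprintf(
    "<focal_result> focal_bp %s: %d retained samples (%d SNPs in window)\n  mean theta %.4g, mean rho %.4g, mean TMRCA %.3f\n",
    format(x$focal_bp), x$n_retained, length(x$window),
    mean(x$theta), mean(x$rho), mean(x$tmrca)
  ))
  invisible(x)
}

#' Tidy the retained samples of a focal-point run
#'
#' @param x a `focal_result`.
#' @param ... unused.
#' @return A tibble with one row per retained sample: `sample`, `theta`,
#'   `rho`, `tmrca`, `rf_prev` (Robinson-Foulds distance to the previous
#'   retained tree, a mixing diagnostic).
#' @export
tidy.focal_result <- function(x, ...) {
  tibble::tibble(
    sample = seq_len(x$n_retained),
    theta = x$theta, rho = x$rho, tmrca = x$tmrca, rf_prev = x$rf_prev
  )
}

#' @export
glance.focal_result <- function(x, ...) {
  tibble::tibble(
    focal_bp = x$focal_bp,
    n_snps_window = length(x$window),
    n_retained = x$n_retained,
    mean_theta = mean(x$theta),
    mean_rho = mean(x$rho),
    mean_tmrca = mean(x$tmrca),
    accept_overall = sum(x$acceptance$accepts) / sum(x$acceptance$attempts)
  )
}

#' Traceplots for a focal-point run
#'
#' @param object a `focal_result`.
#' @param ... unused.
#' @return A ggplot with one panel per retained quantity (theta, rho, TMRCA,
#'   RF distance between successive retained trees).
#' @method autoplot focal_result
#' @export
autoplot.focal_result <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), -"sample",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey25") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "retained sample", y = NULL,
                  title = sprintf("Focal point %s", format(object$focal_bp))) +
    ggplot2::theme_minimal()
}
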