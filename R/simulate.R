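#' Synthetic case/control scenario
#'
#' Study conditions for the coalescent case/control panel generator: a focal
#' genealogy carries a planted causal variant; each haplotype's disease label
#' follows a two-point penetrance on carrier status; marker mutations fall on
#' the focal tree with a probability that decays with distance from the causal
#' site, otherwise on an independent genealogy, so allelic association with
#' the causal variant decays with distance.
#'
#' Defaults: 25 cases / 25 controls, 20 SNPs on a 5 kb region with
#' `rho_true = 4e-4` (the scaled recombination rate implied by 1 cM/Mb at
#' Ne = 10,000); the linkage-decay scale `2/(rho_true * E[T_total])` is then
#' roughly 560 bp, so the region contains both tightly linked and effectively
#' unlinked markers.
#'
#' @param n_case,n_control haplotype counts.
#' @param n_snps number of marker SNPs.
#' @param region_bp region length in base pairs.
#' @param theta_true nominal scaled mutation rate (recorded for reference; the
#'   generator places exactly one mutation per ascertained marker).
#' @param rho_true scaled recombination rate per adjacent bp pair per
#'   coalescent unit.
#' @param causal_freq_range interval in (0,1) for the causal allele frequency.
#' @param penetrance `c(g0, g1)`: case probability for non-carrier / carrier
#'   haplotypes, `g1 >= g0`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `synth_scenario`.
#' @export
synth_scenario <- function(n_case = 25, n_control = 25, n_snps = 20,
                           region_bp = 5000, theta_true = 1, rho_true = 4e-4,
                           causal_freq_range = c(0.4, 0.6),
                           penetrance = c(0.1, 0.9), seed = NULL) {
  stopifnot(n_case >= 1, n_control >= 1, n_snps >= 1, region_bp > n_snps,
            theta_true > 0, rho_true >= 0)
  if (length(causal_freq_range) != 2L || causal_freq_range[1] <= 0 ||
      causal_freq_range[2] >= 1 || diff(causal_freq_range) < 0) {
    stop("causal_freq_range must be an interval inside (0, 1)")
  }
  if (length(penetrance) != 2L || any(penetrance < 0) || any(penetrance > 1) ||
      penetrance[2] < penetrance[1]) {
    stop("penetrance must be c(g0, g1) with g1 >= g0 in [0, 1]")
  }
  structure(
    list(n_case = as.integer(n_case), n_control = as.integer(n_control),
         n_snps = as.integer(n_snps), region_bp = as.integer(region_bp),
         theta_true = theta_true, rho_true = rho_true,
         causal_freq_range = causal_freq_range, penetrance = penetrance,
         seed = seed),
    class = "synth_scenario"
  )
}

#' Simulate a case/control haplotype panel with a planted causal variant
#'
#' Generation steps: (a) draw a focal coalescent tree on all haplotypes;
#' (b) pick a branch whose descendant frequency lies in
#' `causal_freq_range` (uniformly among eligible branches; the tree is
#' redrawn, up to 1000 times, if none qualifies) — its descendants are the
#' carriers; (c) draw case labels by penetrance and redraw the whole labelling
#' (up to 10,000 times) until the case count is exactly `n_case`; (d) place
#' markers uniformly in the region and drop each marker's single mutation on
#' the focal tree with probability `exp(-rho_true * d * T_total / 2)` (branch
#' chosen proportionally to length), where `d` is the marker's distance to the
#' causal site and `T_total` the focal tree's total branch length, otherwise
#' on an independent coalescent tree.
#'
#' @param scenario a [synth_scenario].
#' @return A list: `data` (a [hap_data]; haplotypes sorted so tip `i` of the
#'   focal tree is row `i`), `tree` (the true focal `phylo`), `causal_bp`
#'   (causal position), `carriers` (tip indices carrying the causal allele).
#' @export
simulate_case_control <- function(scenario) {
  stopifnot(inherits(scenario, "synth_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n_case + scenario$n_control
  lo <- scenario$causal_freq_range[1]
  hi <- scenario$causal_freq_range[2]

  # (a)+(b) focal tree with an eligible causal branch
  arr <- NULL
  causal_node <- NA_integer_
  for (try in seq_len(1000L)) {
    cand <- sample_coal_arrays(n, tip_labels = paste0("h", seq_len(n)))
    root <- arrays_root(cand)
    sizes <- arrays_desc_counts(cand)$size
    elig <- setdiff(which(sizes >= lo * n & sizes <= hi * n), root)
    if (length(elig)) {
      arr <- cand
      causal_node <- if (length(elig) == 1L) elig else sample(elig, 1L)
      break
    }
  }
  if (is.null(arr)) {
    stop("no branch with descendant frequency in causal_freq_range after 1000 tree redraws")
  }
  carriers <- descendant_tips(arr, causal_node)

  # (c) penetrance labelling conditional on the case margin
  g <- scenario$penetrance
  pcase <- ifelse(seq_len(n) %in% carriers, g[2], g[1])
  phen <- NULL
  for (try in seq_len(10000L)) {
    lab <- as.integer(runif(n) < pcase)
    if (sum(lab) == scenario$n_case) {
      phen <- lab
      break
    }
  }
  if (is.null(phen)) {
    stop("could not match the case count in 10,000 penetrance labellings")
  }

  # (d) markers: position, linked/unlinked tree, one mutation each
  positions <- sort(sample.int(scenario$region_bp, scenario$n_snps))
  causal_bp <- sample.int(scenario$region_bp, 1L)
  ttot <- total_branch_length(arr)
  alleles <- matrix(0L, n, scenario$n_snps)
  for (j in seq_len(scenario$n_snps)) {
    d <- abs(positions[j] - causal_bp)
    linked <- runif(1) < exp(-scenario$rho_true * d * ttot / 2)
    tr <- if (linked) arr else sample_coal_arrays(n)
    node <- sample_branch_by_length(tr)
    alleles[seq_len(n) %in% descendant_tips(tr, node), j] <- 1L
  }

  data <- hap_data(alleles, positions, phen,
                   haplotype_ids = paste0("h", seq_len(n)))
  list(
    data = data,
    tree = arrays_to_phylo(arr),
    causal_bp = causal_bp,
    carriers = carriers
  )
}

descendant_tips <- function(arr, node) {
  n <- arr$n_tips
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, arr$child1[v], arr$child2[v])
  }
  sort(out)
}

total_branch_length <- function(arr) {
  root <- arrays_root(arr)
  nodes <- setdiff(seq_len(2L * arr$n_tips - 1L), root)
  sum(arr$time[arr$parent[nodes]] - arr$time[nodes])
}

# sample a non-root node (= the branch above it) proportionally to its length
sample_branch_by_length <- function(arr) {
  root <- arrays_root(arr)
  nodes <- setdiff(seq_len(2L * arr$n_tips - 1L), root)
  len <- arr$time[arr$parent[nodes]] - arr$time[nodes]
  nodes[sample.int(length(nodes), 1L, prob = len)]
}
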