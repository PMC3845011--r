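#' Configuration for a region-level analysis
#'
#' Defaults follow the method's standard analysis: focal points spaced evenly
#' through the region, a 100 kb total window around each focal point expanded
#' to the nearest `min_snps` SNPs where sparse, 5% bipartition eligibility,
#' and M = 35,000 draws from the coalescent prior shared by all focal points
#' (the prior null does not depend on the focal point).
#'
#' @param n_focal_points number of focal points.
#' @param window_bp total window width in bp (SNPs within `window_bp/2` of
#'   the focal point are included).
#' @param min_snps minimum number of SNPs per window.
#' @param min_frac bipartition eligibility fraction.
#' @param prior_m number of coalescent prior draws for the null.
#' @param sampler a [sampler_config] applied at every focal point.
#' @param alpha nominal significance level used for plot thresholds.
#' @param seed master seed; per-focal seeds are derived as
#'   `bitwXor(seed, focal_index)`.
#' @return An object of class `region_config`.
#' @export
region_config <- function(n_focal_points = 100, window_bp = 100000,
                          min_snps = 20, min_frac = 0.05, prior_m = 35000,
                          sampler = sampler_config(), alpha = 0.05,
                          seed = 1) {
  stopifnot(n_focal_points >= 1, window_bp > 0, min_snps >= 2,
            min_frac >= 0, min_frac < 0.5, prior_m >= 1,
            inherits(sampler, "sampler_config"), alpha > 0, alpha < 1)
  structure(
    list(n_focal_points = as.integer(n_focal_points),
         window_bp = window_bp, min_snps = as.integer(min_snps),
         min_frac = min_frac, prior_m = as.integer(prior_m),
         sampler = sampler, alpha = alpha, seed = as.integer(seed)),
    class = "region_config"
  )
}

#' Evenly spaced focal points across a region
#'
#' Grid centers: the endpoints are inset by half a spacing, so `k` points
#' tile the region evenly.
#'
#' @param region_start,region_end region bounds (bp), `region_end` larger.
#' @param k number of focal points.
#' @return Numeric vector of `k` positions.
#' @export
focal_grid <- function(region_start, region_end, k) {
  if (k < 1) stop("k must be at least 1")
  if (region_end <= region_start) stop("region_end must exceed region_start")
  spacing <- (region_end - region_start) / k
  region_start + (seq_len(k) - 0.5) * spacing
}

#' Select the SNP window around a focal point
#'
#' All SNPs within `window_bp/2` of the focal point; when fewer than
#' `min_snps` fall inside, the `min_snps` SNPs closest to the focal point are
#' used instead (distance ties resolved toward the lower position). Near the
#' region edges the window is clipped, not re-centered.
#'
#' @param positions ascending SNP positions (bp).
#' @param focal_bp focal position.
#' @param window_bp total window width.
#' @param min_snps minimum SNP count; must not exceed the number of SNPs.
#' @return Sorted integer indices of the selected SNPs (always contiguous).
#' @export
select_window <- function(positions, focal_bp, window_bp, min_snps) {
  L <- length(positions)
  if (min_snps > L) stop("min_snps exceeds the number of SNPs")
  inside <- which(abs(positions - focal_bp) <= window_bp / 2)
  if (length(inside) >= min_snps) return(inside)
  ord <- order(abs(positions - focal_bp), positions)
  sort(ord[seq_len(min_snps)])
}

#' Convert a genetic-map rate to the scaled recombination rate
#'
#' Converts cM/Mb to the population-scaled recombination rate per pair of
#' adjacent base pairs per unit of coalescent time (1 unit = 2Ne
#' generations): 1 cM/Mb is a per-generation, per-bp crossover probability of
#' about 1e-8, and the scaled rate is `rho = 4 Ne c`.
#'
#' @param rate_cM_per_Mb genetic-map rate (cM/Mb), nonnegative.
#' @param ne effective population size (default 10,000).
#' @return The scaled rate rho; 1 cM/Mb at Ne = 10,000 gives 4e-4.
#' @export
convert_map_rate <- function(rate_cM_per_Mb, ne = 10000) {
  if (any(rate_cM_per_Mb < 0)) stop("rate must be nonnegative")
  if (any(ne <= 0)) stop("ne must be positive")
  4 * ne * (rate_cM_per_Mb * 1e-8)
}

#' Run the full tree-based association analysis across a region
#'
#' For each focal point on the grid: select the SNP window, run the MCMC
#' sampler, compute the bipartition maximum-correlation statistic on every
#' retained tree, convert to latent p-values against one shared coalescent
#' prior sample, and summarize. A permutation companion (the statistic of a
#' single label permutation against the same retained trees) is produced as a
#' null diagnostic. Fully reproducible from the master seed; each focal point
#' uses the derived seed `bitwXor(seed, focal_index)`, so results do not
#' depend on execution order.
#'
#' @param data a [hap_data] panel.
#' @param config a [region_config].
#' @param out_dir optional directory; when given, writes `results.tsv`,
#'   `permutation.tsv`, `acceptance.tsv` and per-focal Newick tree streams.
#' @return An object of class `region_result`: `results` and `permutation`
#'   summary tibbles (one row per focal point), the shared `prior` sample,
#'   the per-focal `focal` results, the per-focal fuzzy p-values (`fuzzy`,
#'   and `fuzzy_perm` for the permuted labels), and the `config`.
#' @export
run_region <- function(data, config, out_dir = NULL) {
  stopifnot(inherits(data, "hap_data"), inherits(config, "region_config"))
  check_two_classes(data$phenotype)
  n <- nrow(data$alleles)
  set.seed(config$seed)
  prior <- sample_prior_statistics(n, data$phenotype, config$prior_m,
                                   config$min_frac)
  perm <- sample.int(n)
  phen_perm <- data$phenotype[perm]
  grid <- focal_grid(min(data$positions), max(data$positions),
                     config$n_focal_points)
  focal_results <- vector("list", length(grid))
  fuzzy <- vector("list", length(grid))
  fuzzy_perm <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  perm_rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg_i <- config$sampler
    cfg_i$seed <- bitwXor(config$seed, i)
    window <- select_window(data$positions, grid[i], config$window_bp,
                            config$min_snps)
    fr <- withCallingHandlers(
      run_sampler(data, grid[i], window, cfg_i),
      error = function(e) stop("focal point ", i, " (", grid[i], " bp): ",
                               conditionMessage(e))
    )
    focal_results[[i]] <- fr
    stats <- focal_statistics(fr, data$phenotype, config$min_frac)
    stats_perm <- focal_statistics(fr, phen_perm, config$min_frac)
    rates <- summarize_rates(fr)
    fz <- fuzzy_or_null(stats, prior)
    fz_perm <- fuzzy_or_null(stats_perm, prior)
    fuzzy[[i]] <- fz
    fuzzy_perm[[i]] <- fz_perm
    rows[[i]] <- summary_row(grid[i], length(window), rates, fz,
                             fr$n_retained)
    perm_rows[[i]] <- summary_row(grid[i], length(window), rates, fz_perm,
                                  fr$n_retained)
  }
  results <- dplyr::bind_rows(rows)
  permutation <- dplyr::bind_rows(perm_rows)
  attr(results, "m_prior") <- config$prior_m
  attr(permutation, "m_prior") <- config$prior_m
  out <- structure(
    list(results = results, permutation = permutation, prior = prior,
         focal = focal_results, fuzzy = fuzzy, fuzzy_perm = fuzzy_perm,
         config = config, perm = perm),
    class = "region_result"
  )
  if (!is.null(out_dir)) write_region_outputs(out, out_dir)
  out
}

# statistic on every retained tree of a focal run (fast array path);
# trees with no eligible bipartition yield NA and are dropped by the caller
focal_statistics <- function(fr, phenotype, min_frac) {
  n <- (nrow(fr$parent) + 1L) / 2L
  vapply(seq_len(fr$n_retained), function(s) {
    arr <- parent_to_arrays(fr$parent[, s], fr$time[, s], n, fr$tip_labels)
    max_stat_arrays(arr, phenotype, min_frac)
  }, numeric(1))
}

fuzzy_or_null <- function(stats, prior) {
  stats <- stats[!is.na(stats)]
  if (!length(stats)) return(NULL)
  fuzzy_pvalue(stats, prior)
}

summary_row <- function(focal_bp, n_snps, rates, fz, n_retained) {
  if (is.null(fz)) {
    # no eligible bipartition at this focal point: reported as missing
    return(tibble::tibble(
      focal_bp = focal_bp, n_snps_window = n_snps,
      mean_rho = rates$mean_rho, mean_theta = rates$mean_theta,
      median_latent_p = NA_real_, q25 = NA_real_, q75 = NA_real_,
      q90 = NA_real_, n_tree_samples = 0L, zero_replaced = NA
    ))
  }
  tibble::tibble(
    focal_bp = focal_bp, n_snps_window = n_snps,
    mean_rho = rates$mean_rho, mean_theta = rates$mean_theta,
    median_latent_p = fz$summaries$median,
    q25 = fz$summaries$q25, q75 = fz$summaries$q75, q90 = fz$summaries$q90,
    n_tree_samples = length(fz$latent_p),
    zero_replaced = fz$zero_replaced_for_log
  )
}

#' Write the per-focal-point results table
#'
#' Tab-separated, deterministic column order (`focal_bp`, `n_snps_window`,
#' `mean_rho`, `mean_theta`, `median_latent_p`, `q25`, `q75`, `q90`,
#' `n_tree_samples`, `zero_replaced`). Latent-p summaries that are exactly
#' zero are written as the log-plotting replacement `1/M` with the
#' `zero_replaced` flag set.
#'
#' @param rows tibble of per-focal summaries (as in `region_result$results`).
#' @param path output path.
#' @param m_prior the prior sample size M used for the zero replacement;
#'   defaults to the `m_prior` attribute attached by [run_region()].
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path, m_prior = attr(rows, "m_prior")) {
  cols <- c("focal_bp", "n_snps_window", "mean_rho", "mean_theta",
            "median_latent_p", "q25", "q75", "q90", "n_tree_samples")
  if (is.null(rows) || !nrow(rows)) stop("no rows to write")
  if (!all(cols %in% names(rows))) {
    stop("missing columns: ", paste(setdiff(cols, names(rows)), collapse = ", "))
  }
  if (is.null(m_prior)) stop("m_prior is required for zero replacement")
  out <- rows[cols]
  if (!all(vapply(out, function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite summary value")
  }
  pcols <- c("median_latent_p", "q25", "q75", "q90")
  replaced <- rep(FALSE, nrow(out))
  for (cc in pcols) {
    z <- out[[cc]] == 0
    replaced <- replaced | z
    out[[cc]][z] <- 1 / m_prior
  }
  out$zero_replaced <- replaced
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_region_outputs <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- !is.na(x$results$median_latent_p)
  write_results_table(x$results[ok, ], file.path(out_dir, "results.tsv"),
                      m_prior = x$config$prior_m)
  write_results_table(x$permutation[ok, ], file.path(out_dir, "permutation.tsv"),
                      m_prior = x$config$prior_m)
  acc <- dplyr::bind_rows(lapply(seq_along(x$focal), function(i) {
    dplyr::mutate(x$focal[[i]]$acceptance, focal_index = i, .before = 1)
  }))
  utils::write.table(acc, file.path(out_dir, "acceptance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_along(x$focal)) {
    trees <- sampled_trees(x$focal[[i]])
    writeLines(vapply(trees, write_newick, character(1)),
               file.path(out_dir, sprintf("trees_focal_%03d.nwk", i)))
  }
  invisible(out_dir)
}

#' @export
print.region_result <- function(x, ...) {
  cat(sprintf(
    "<region_result> %d focal points, %d haplotypes, M = %d prior draws\n",
    nrow(x$results), length(x$prior$phenotype), x$config$prior_m
  ))
  best <- which.min(x$results$median_latent_p)
  if (length(best)) {
    cat(sprintf("  smallest median latent p: %.4g at %s bp\n",
                x$results$median_latent_p[best], format(x$results$focal_bp[best])))
  }
  invisible(x)
}

#' @export
tidy.region_result <- function(x, ...) x$results

#' @export
glance.region_result <- function(x, ...) {
  best <- which.min(x$results$median_latent_p)
  tibble::tibble(
    n_focal_points = nrow(x$results),
    peak_focal_bp = x$results$focal_bp[best],
    peak_median_latent_p = x$results$median_latent_p[best],
    bonferroni = bonferroni_threshold(x$config$alpha, nrow(x$results)),
    mean_rho_region = mean(x$results$mean_rho),
    mean_theta_region = mean(x$results$mean_theta)
  )
}

#' Association curve across the region
#'
#' Plots `-log10` of the median latent p-value by focal point, with the
#' uncorrected and Bonferroni-corrected thresholds, in the style of standard
#' regional association plots. Zero medians are drawn at the `1/M`
#' replacement value.
#'
#' @param object a `region_result`.
#' @param permutation if `TRUE`, plot the permutation companion instead.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot region_result
#' @export
autoplot.region_result <- function(object, permutation = FALSE, ...) {
  tab <- if (permutation) object$permutation else object$results
  m <- object$config$prior_m
  tab <- dplyr::mutate(
    tab,
    p_plot = pmax(.data$median_latent_p, 1 / m),
    neglog = -log10(.data$p_plot)
  )
  k <- nrow(tab)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$focal_bp, y = .data$neglog)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(object$config$alpha),
                        linetype = 2) +
    ggplot2::geom_hline(
      yintercept = -log10(bonferroni_threshold(object$config$alpha, k)),
      linetype = 3
    ) +
    ggplot2::labs(
      x = "focal point (bp)",
      y = expression(-log[10] ~ "median latent p"),
      title = if (permutation) "Permutation null" else "Tree-based association"
    ) +
    ggplot2::theme_minimal()
}
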