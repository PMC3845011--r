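#' Latent p-value of an association statistic
#'
#' For a statistic value `t_c` computed on one posterior tree, the latent
#' p-value is the fraction of prior (neutral-coalescent) statistic values at
#' least as large: `p = sum(T_u >= t_c) / M` (inclusive inequality).
#'
#' @param t_c statistic value(s) from posterior trees; vectorized.
#' @param prior a `prior_sample` from [sample_prior_statistics()].
#' @return Latent p-value(s), each on the grid `0, 1/M, ..., 1`.
#' @export
latent_pvalue <- function(t_c, prior) {
  stopifnot(inherits(prior, "prior_sample"))
  srt <- sort(prior$statistics)
  m <- prior$m
  # inclusive >=: count = m - #{prior < t_c}
  (m - findInterval(t_c, srt, left.open = TRUE)) / m
}

#' Fuzzy p-value: the posterior distribution of latent p-values
#'
#' Computes the latent p-value for the statistic on every posterior-sampled
#' tree and summarizes the resulting distribution (the fuzzy p-value) by its
#' empirical median, quartiles and 90th percentile. Summaries that are exactly
#' zero cannot be drawn on a log scale; `summaries_log` replaces them by
#' `1/M` and `zero_replaced_for_log` records whether any replacement was
#' needed.
#'
#' @param t_c statistic values over the `N` posterior trees.
#' @param prior a `prior_sample`.
#' @return An object of class `fuzzy_p`: `latent_p`, `m_prior`, `summaries`
#'   (median, q25, q75, q90), `summaries_log`, `zero_replaced_for_log`.
#' @export
fuzzy_pvalue <- function(t_c, prior) {
  if (length(t_c) < 1L) stop("need at least one posterior statistic")
  p <- latent_pvalue(t_c, prior)
  qs <- quantile(p, probs = c(0.5, 0.25, 0.75, 0.9), names = FALSE)
  summaries <- list(median = qs[1], q25 = qs[2], q75 = qs[3], q90 = qs[4])
  repl <- vapply(summaries, function(v) v == 0, logical(1))
  summaries_log <- summaries
  summaries_log[repl] <- 1 / prior$m
  structure(
    list(
      latent_p = p,
      m_prior = prior$m,
      summaries = summaries,
      summaries_log = summaries_log,
      zero_replaced_for_log = any(repl)
    ),
    class = "fuzzy_p"
  )
}

#' @export
print.fuzzy_p <- function(x, ...) {
  s <- x$summaries
  cat(sprintf(
    "<fuzzy_p> N = %d latent p-values (M = %d prior draws)\n  median %.4g  IQR [%.4g, %.4g]  q90 %.4g%s\n",
    length(x$latent_p), x$m_prior, s$median, s$q25, s$q75, s$q90,
    if (x$zero_replaced_for_log) "  (zero summaries -> 1/M on log scale)" else ""
  ))
  invisible(x)
}

#' @describeIn fuzzy_pvalue One row per posterior tree with its latent p-value.
#' @param x a `fuzzy_p` object.
#' @param ... unused.
#' @export
tidy.fuzzy_p <- function(x, ...) {
  tibble::tibble(
    tree = seq_along(x$latent_p),
    latent_p = x$latent_p
  )
}

#' @describeIn fuzzy_pvalue One-row summary (median, quartiles, q90, flag).
#' @export
glance.fuzzy_p <- function(x, ...) {
  tibble::tibble(
    n_trees = length(x$latent_p),
    m_prior = x$m_prior,
    median = x$summaries$median,
    q25 = x$summaries$q25,
    q75 = x$summaries$q75,
    q90 = x$summaries$q90,
    zero_replaced_for_log = x$zero_replaced_for_log
  )
}

#' Permutation diagnostic for the fuzzy p-value
#'
#' Permutes the case/control labels once, then recomputes the association
#' statistic on the previously sampled trees (the tree sampling step does not
#' use phenotype information, so the trees are reused, not resampled) and
#' returns the fuzzy p-value under the permuted labels. Under the null this
#' should show no association signal.
#'
#' @param trees list of `phylo` objects sharing one tip set.
#' @param phenotype 0/1 labels per tip (named or in tip order).
#' @param prior a `prior_sample`.
#' @param min_frac eligibility fraction.
#' @param perm optional explicit permutation (integer vector); by default a
#'   uniform random permutation is drawn with R's RNG.
#' @return A `fuzzy_p` object for the permuted labels.
#' @export
permutation_fuzzy <- function(trees, phenotype, prior, min_frac = 0.05,
                              perm = NULL) {
  if (!length(trees)) stop("need at least one tree")
  labels <- trees[[1]]$tip.label
  y <- bind_phenotype(phenotype, labels)
  if (is.null(perm)) perm <- sample.int(length(y))
  yp <- setNames(y[perm], labels)
  t_c <- vapply(trees, max_correlation_statistic, numeric(1),
                phenotype = yp, min_frac = min_frac)
  fuzzy_pvalue(t_c, prior)
}

#' Histogram of the latent p-value distribution
#'
#' @param object a `fuzzy_p` object.
#' @param bins number of histogram bins.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fuzzy_p
#' @export
autoplot.fuzzy_p <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$latent_p)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = object$summaries$median,
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "latent p-value", y = "posterior trees",
                  title = "Fuzzy p-value",
                  subtitle = sprintf("median = %.3g (dashed)",
                                     object$summaries$median)) +
    ggplot2::theme_minimal()
}
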