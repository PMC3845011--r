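#' Single-SNP Fisher exact tests
#'
#' The conventional single-locus comparator: for each SNP, a two-sided Fisher
#' exact test of the 2x2 allele-by-case/control table (two-sided by summing
#' hypergeometric outcomes no more probable than the observed one).
#' Monomorphic SNPs carry no information; they are reported with `p = 1` and
#' flagged rather than dropped, so the output always has one row per SNP.
#'
#' @param data a [hap_data] panel with both phenotype classes present.
#' @return A tibble with columns `snp`, `position`, `p`, `monomorphic`.
#' @export
fisher_exact_per_snp <- function(data) {
  stopifnot(inherits(data, "hap_data"))
  check_two_classes(data$phenotype)
  y <- data$phenotype
  L <- ncol(data$alleles)
  p <- numeric(L)
  mono <- logical(L)
  for (j in seq_len(L)) {
    a <- data$alleles[, j]
    if (length(unique(a)) < 2L) {
      p[j] <- 1
      mono[j] <- TRUE
    } else {
      tab <- table(factor(a, levels = 0:1), factor(y, levels = 0:1))
      p[j] <- fisher.test(tab)$p.value
    }
  }
  tibble::tibble(
    snp = seq_len(L),
    position = data$positions,
    p = p,
    monomorphic = mono
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha nominal level in (0, 1).
#' @param k number of tests (SNPs or focal points), at least 1.
#' @return `alpha / k`.
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(k) || k < 1) stop("k must be at least 1")
  alpha / k
}
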