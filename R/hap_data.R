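#' Phased case/control haplotype panel
#'
#' Container for a phased binary haplotype panel: an `H x L` 0/1 allele
#' matrix, strictly ascending base-pair positions, and a binary phenotype per
#' haplotype (1 = case; in a trio design the transmitted haplotypes are the
#' cases and the untransmitted haplotypes the controls).
#'
#' @param alleles integer/numeric matrix of 0/1 alleles, one row per haplotype,
#'   one column per SNP.
#' @param positions integer vector of 1-based base-pair coordinates, strictly
#'   increasing, one per SNP.
#' @param phenotype vector of 0/1 labels, one per haplotype (1 = case).
#' @param haplotype_ids unique labels, one per haplotype; defaults to the
#'   rownames of `alleles` or `h1 ... hH`.
#'
#' @return An object of class `hap_data`.
#' @export
hap_data <- function(alleles, positions, phenotype, haplotype_ids = NULL) {
  if (!is.matrix(alleles)) stop("`alleles` must be a matrix")
  storage.mode(alleles) <- "integer"
  H <- nrow(alleles)
  L <- ncol(alleles)
  if (H < 4L) stop("need at least 4 haplotypes")
  if (L < 1L) stop("need at least 1 SNP")
  if (anyNA(alleles) || !all(alleles %in% c(0L, 1L))) {
    stop("alleles must all be 0 or 1")
  }
  positions <- as.numeric(positions)
  if (length(positions) != L) stop("length(positions) must equal ncol(alleles)")
  if (anyNA(positions) || any(diff(positions) <= 0)) {
    stop("positions not ascending")
  }
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != H) stop("length(phenotype) must equal nrow(alleles)")
  if (anyNA(phenotype) || !all(phenotype %in% c(0L, 1L))) {
    stop("phenotype must be 0/1")
  }
  if (is.null(haplotype_ids)) haplotype_ids <- rownames(alleles)
  if (is.null(haplotype_ids)) haplotype_ids <- paste0("h", seq_len(H))
  haplotype_ids <- as.character(haplotype_ids)
  if (length(haplotype_ids) != H || anyDuplicated(haplotype_ids)) {
    stop("haplotype_ids must be unique, one per haplotype")
  }
  rownames(alleles) <- haplotype_ids
  structure(
    list(
      alleles = alleles,
      positions = positions,
      phenotype = phenotype,
      haplotype_ids = haplotype_ids
    ),
    class = "hap_data"
  )
}

#' @export
print.hap_data <- function(x, ...) {
  cat(sprintf(
    "<hap_data> %d haplotypes x %d SNPs, %d cases / %d controls, span %s-%s bp\n",
    nrow(x$alleles), ncol(x$alleles), sum(x$phenotype == 1L),
    sum(x$phenotype == 0L), format(min(x$positions)), format(max(x$positions))
  ))
  invisible(x)
}

#' @export
dim.hap_data <- function(x) dim(x$alleles)

# error unless the panel has both cases and controls
check_two_classes <- function(phenotype) {
  if (length(unique(phenotype)) < 2L) {
    stop("phenotype is constant: need at least one case and one control")
  }
  invisible(phenotype)
}

#' Tidy a haplotype panel into long format
#'
#' @param x a [hap_data] object.
#' @param ... unused.
#' @return A tibble with one row per haplotype/SNP combination: `haplotype`,
#'   `phenotype`, `position`, `allele`.
#' @export
tidy.hap_data <- function(x, ...) {
  H <- nrow(x$alleles)
  L <- ncol(x$alleles)
  tibble::tibble(
    haplotype = rep(x$haplotype_ids, times = L),
    phenotype = rep(x$phenotype, times = L),
    position = rep(x$positions, each = H),
    allele = as.integer(x$alleles)
  )
}

#' Read a haplotype panel
#'
#' Two on-disk formats are supported. `"matrix"` is a whitespace-separated
#' text layout: the first row holds the L base-pair positions; each following
#' row holds a haplotype id, its 0/1 phenotype, and L alleles. `"vcf"` reads a
#' phased VCF (GT field, `|` separator only); each diploid sample contributes
#' two haplotypes named `<sample>_1` and `<sample>_2`, and the phenotype must
#' be supplied in a side table.
#'
#' @param path file path.
#' @param format `"matrix"` or `"vcf"`.
#' @param phenotype_file for `format = "vcf"`: path to a tab-separated table
#'   with columns `haplotype_id` and `phenotype` covering every haplotype.
#' @return A validated [hap_data] object.
#' @export
read_haplotypes <- function(path, format = c("matrix", "vcf"),
                            phenotype_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix") read_haplotypes_matrix(path)
  else read_haplotypes_vcf(path, phenotype_file)
}

read_haplotypes_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("parse error at line 1: need positions + rows")
  positions <- suppressWarnings(as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (anyNA(positions)) stop("parse error at line 1: non-numeric position")
  L <- length(positions)
  body <- lines[-1]
  ids <- character(length(body))
  phen <- integer(length(body))
  alleles <- matrix(NA_integer_, length(body), L)
  for (i in seq_along(body)) {
    fields <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(fields) != L + 2L) {
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   i + 1L, L + 2L, length(fields)))
    }
    ids[i] <- fields[1]
    phen[i] <- suppressWarnings(as.integer(fields[2]))
    row <- suppressWarnings(as.integer(fields[-(1:2)]))
    if (anyNA(row) || is.na(phen[i])) {
      stop(sprintf("parse error at line %d: non-integer value", i + 1L))
    }
    alleles[i, ] <- row
  }
  rownames(alleles) <- ids
  hap_data(alleles, positions, phen, ids)
}

read_haplotypes_vcf <- function(path, phenotype_file) {
  if (is.null(phenotype_file)) {
    stop("validation error: phenotype_file is required for VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  if (any(grepl(",", alt)) || any(nchar(alt) != 1L) || any(nchar(ref) != 1L)) {
    stop("multiallelic or non-SNP record in VCF")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  if (any(grepl("/", gt, fixed = TRUE)) || anyNA(gt)) {
    stop("unphased or missing genotype in VCF (only '|'-phased GT accepted)")
  }
  samples <- colnames(gt)
  pos <- as.numeric(fix[, "POS"])
  ord <- order(pos)
  pos <- pos[ord]
  gt <- gt[ord, , drop = FALSE]
  hapmat <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = length(pos))
  ids <- character(2L * length(samples))
  # gt is SNP x sample; each sample contributes two haplotype rows
  for (s in seq_along(samples)) {
    col <- gt[, s]
    parts <- strsplit(col, "|", fixed = TRUE)
    a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    if (anyNA(a1) || anyNA(a2)) stop("malformed GT for sample ", samples[s])
    hapmat[2L * s - 1L, ] <- a1
    hapmat[2L * s, ] <- a2
    ids[2L * s - 1L] <- paste0(samples[s], "_1")
    ids[2L * s] <- paste0(samples[s], "_2")
  }
  ptab <- utils::read.table(phenotype_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("haplotype_id", "phenotype") %in% names(ptab))) {
    stop("phenotype table needs columns haplotype_id, phenotype")
  }
  idx <- match(ids, ptab$haplotype_id)
  if (anyNA(idx)) {
    stop("validation error: missing phenotype for haplotype ",
         ids[which(is.na(idx))[1]])
  }
  rownames(hapmat) <- ids
  hap_data(hapmat, pos, ptab$phenotype[idx], ids)
}

#' Write a haplotype panel in matrix-text format
#'
#' @param x a [hap_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(x, path) {
  stopifnot(inherits(x, "hap_data"))
  lines <- c(
    paste(format(x$positions, scientific = FALSE, trim = TRUE), collapse = " "),
    vapply(seq_len(nrow(x$alleles)), function(i) {
      paste(c(x$haplotype_ids[i], x$phenotype[i], x$alleles[i, ]),
            collapse = " ")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
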