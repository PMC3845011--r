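test_that("matrix-text haplotype panels round-trip exactly", {
  alle <- matrix(c(0L, 1L, 1L, 0L,
                   1L, 1L, 0L, 0L,
                   0L, 0L, 1L, 1L), nrow = 4)
  d <- hap_data(alle, c(120, 5000, 9000), c(1, 1, 0, 0),
                haplotype_ids = c("a", "b", "c", "d"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_haplotypes(d, path)
  d2 <- read_haplotypes(path, format = "matrix")
  expect_identical(d2$alleles, d$alleles)
  expect_identical(d2$positions, d$positions)
  expect_identical(d2$phenotype, d$phenotype)
  expect_identical(d2$haplotype_ids, d$haplotype_ids)
})

test_that("malformed haplotype files are rejected with located errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("100 90", "a 1 0 1", "b 1 1 0", "c 0 0 0", "d 0 1 1"), path)
  expect_error(read_haplotypes(path), "positions not ascending")

  writeLines(c("100 200", "a 1 0 1", "b 1 1 0", "c 0 0 0", "d 0 1"), path)
  expect_error(read_haplotypes(path), "line 5")

  expect_error(
    hap_data(matrix(0:1, 4, 2), c(1, 2), c(1, 0, 1, 2)),
    "phenotype"
  )
  expect_error(
    hap_data(matrix(2L, 4, 2), c(1, 2), c(1, 0, 1, 0)),
    "0 or 1"
  )
})

test_that("phased VCF input yields two haplotypes per diploid sample", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "5\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "5\t250\t.\tC\tT\t.\tPASS\t.\tGT\t1|0\t0|0"
  ), vcf)
  phen <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("haplotype_id\tphenotype", "S1_1\t1", "S1_2\t0",
               "S2_1\t1", "S2_2\t0"), phen)
  d <- read_haplotypes(vcf, format = "vcf", phenotype_file = phen)
  expect_equal(nrow(d$alleles), 4L)
  expect_equal(d$positions, c(100, 250))
  expect_equal(unname(d$alleles["S1_1", ]), c(0L, 1L))
  expect_equal(unname(d$alleles["S2_2", ]), c(1L, 0L))

  # unphased genotypes are rejected
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "5\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1"
  ), vcf)
  expect_error(read_haplotypes(vcf, format = "vcf", phenotype_file = phen),
               "unphased")
  # missing phenotype entry is a validation error
  writeLines(c("haplotype_id\tphenotype", "S1_1\t1", "S1_2\t0", "S2_1\t1"),
             phen)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "5\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1"
  ), vcf)
  expect_error(read_haplotypes(vcf, format = "vcf", phenotype_file = phen),
               "missing phenotype")
})

test_that("newick parsing recovers node times and rejects bad trees", {
  tr <- read_newick("((a:1,b:1):0.5,c:1.5);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tmrca(tr), 1.5)
  tm <- node_times(tr)
  expect_equal(unname(tm[1:3]), c(0, 0, 0))

  expect_error(read_newick("(a:1,b:1,c:1);"), "non-binary")
  expect_error(read_newick("((a:1,b:-1):0.5,c:1.5);"), "negative")
})

test_that("newick writing round-trips topology and node times", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(3:15, 1)
    tr <- sample_coalescent_tree(n)
    tr2 <- read_newick(write_newick(tr))
    expect_identical(rf_distance(tr, tr2), 0L)
    o1 <- sort(node_times(tr))
    o2 <- sort(node_times(tr2))
    expect_lt(max(abs(o1 - o2)), 1e-9)
  }
})

test_that("results tables have fixed columns and flagged zero replacement", {
  rows <- tibble::tibble(
    focal_bp = c(10, 20), n_snps_window = c(5L, 6L),
    mean_rho = c(0.1, 0.2), mean_theta = c(1, 2),
    median_latent_p = c(0, 0.3), q25 = c(0, 0.2), q75 = c(0.1, 0.5),
    q90 = c(0.2, 0.9), n_tree_samples = c(100L, 100L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(rows, path, m_prior = 1000)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(tab), c("focal_bp", "n_snps_window", "mean_rho",
                             "mean_theta", "median_latent_p", "q25", "q75",
                             "q90", "n_tree_samples", "zero_replaced"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$median_latent_p[1], 1 / 1000)
  expect_true(tab$zero_replaced[1])
  expect_false(tab$zero_replaced[2])

  expect_error(write_results_table(rows[0, ], path, m_prior = 1000), "no rows")
  rows$mean_rho[1] <- NaN
  expect_error(write_results_table(rows, path, m_prior = 1000), "non-finite")
})
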