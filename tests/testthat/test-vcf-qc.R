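test_that("VCF round trip preserves genotype content and phase", {
  gm <- random_gm(6, 40, seed = 3, miss = 0.1)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path)
  expect_identical(gm2$haps, gm$haps)
  expect_identical(gm2$pos, gm$pos)
  expect_identical(gm2$chrom, gm$chrom)
  expect_identical(gm2$samples, gm$samples)
  expect_true(gm2$phased)
  expect_identical(attr(gm2, "n_skipped"), 0L)

  gm$phased <- FALSE
  write_vcf(gm, path)
  expect_false(read_vcf(path)$phased)
})

test_that("read_vcf skips multiallelic and indel records and parses phase", {
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1,length=100000>",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
             "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|0",
             "chr1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1\t0|0",
             "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0|1\t0|0",
             "chr1\t400\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  gm <- read_vcf(path)
  expect_equal(n_variants(gm), 2L)
  expect_identical(attr(gm, "n_skipped"), 2L)
  # "0|1" and "1|0" are both heterozygous but with distinct haplotype order
  expect_identical(gm$haps[, 1], c(0L, 1L, 1L, 0L))
  # "./." is missing on both haplotypes; "0/1" marks the file unphased
  expect_identical(gm$haps[, 2], c(NA_integer_, NA_integer_, 0L, 1L))
  expect_false(gm$phased)
  expect_identical(gm$chrom_lengths, c(chr1 = 1e5))
})

test_that("read_vcf reports malformed records with their line number", {
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1"), collapse = "\t"),
             "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
             "chr1\t200\t.\tA\tG\t.\tPASS\t.\tGT")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  expect_error(read_vcf(path), "line 4")
})

test_that("hwe_exact_test matches the enumeration oracle and is symmetric", {
  # all configurations with up to 10 individuals
  for (n in 1:10) {
    for (aa in 0:n) for (het in 0:(n - aa)) {
      AA <- n - aa - het
      expect_equal(hwe_exact_test(AA, het, aa), oracle_hwe(AA, het, aa),
                   tolerance = 1e-12,
                   label = sprintf("hwe(%d,%d,%d)", AA, het, aa))
      expect_identical(hwe_exact_test(AA, het, aa),
                       hwe_exact_test(aa, het, AA))
    }
  }
  expect_identical(hwe_exact_test(5, 0, 0), 1)  # monomorphic
})

test_that("filter_variants applies strict thresholds in order", {
  # 20 samples; craft variants failing each criterion
  s <- 20
  haps <- matrix(0L, 2 * s, 4)
  haps[1:2, 1] <- 1L                      # MAF = 2/40 = 0.05 -> retained
  haps[1, 2] <- 1L                        # MAF = 1/40 = 0.025 -> removed
  haps[seq(1, 16, 2), 3] <- 1L            # 8 hets: HWE fine, MAF 0.2
  # call rate 17/20 = 0.85 -> removed regardless of MAF
  haps[1:6, 4] <- NA_integer_
  haps[7:24, 4] <- rep(c(0L, 1L), 9)
  gm <- make_gm(haps)
  out <- filter_variants(gm)
  rep_ <- attr(out, "filter_report")
  expect_identical(rep_$removed_call_rate, 1L)
  expect_identical(rep_$removed_maf, 1L)
  expect_identical(rep_$retained, 2L)
  expect_identical(rep_$input,
                   rep_$removed_call_rate + rep_$removed_maf +
                     rep_$removed_hwe + rep_$retained)
  expect_identical(out$pos, gm$pos[c(1, 3)])
})

test_that("HWE filter removes extreme heterozygote excess", {
  s <- 30
  haps <- matrix(rep(c(0L, 1L), s), 2 * s, 2)  # every sample het
  # second variant is HWE-consistent at freq 0.5 (half the samples het)
  haps[, 2] <- rep(c(0L, 1L, 0L, 0L, 1L, 1L, 1L, 0L), length.out = 2 * s)
  gm <- make_gm(haps)
  p <- hwe_exact_test(0, s, 0)
  expect_lt(p, 1e-4)
  out <- filter_variants(gm)
  expect_identical(attr(out, "filter_report")$removed_hwe, 1L)
})

test_that("filter_variants is idempotent and report sums on random inputs", {
  for (seed in 1:5) {
    gm <- random_gm(12, 60, seed = seed, miss = 0.15)
    out1 <- filter_variants(gm)
    r1 <- attr(out1, "filter_report")
    expect_identical(r1$input,
                     r1$removed_call_rate + r1$removed_maf +
                       r1$removed_hwe + r1$retained)
    out2 <- filter_variants(out1)
    expect_identical(out2$haps, out1$haps)
    expect_identical(attr(out2, "filter_report")$retained, r1$retained)
  }
})
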