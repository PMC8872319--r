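test_that("identical configs and seeds give bit-identical data and VCFs", {
  cfg <- sim_config(n_samples = 8, chrom_length = 1e6,
                    target_snp_count = 300, seed = 42)
  gm1 <- simulate_neutral(cfg, "mosaic")
  gm2 <- simulate_neutral(cfg, "mosaic")
  expect_identical(gm1, gm2)
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm1, p1); write_vcf(gm2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("switch_rate = 0 makes every sample haplotype a founder copy", {
  cfg <- sim_config(n_samples = 6, chrom_length = 1e6,
                    target_snp_count = 200, founder_haplotypes = 3,
                    switch_rate = 0, seed = 5)
  gm <- simulate_neutral(cfg, "mosaic")
  # with no recombination, at most K distinct haplotypes per chromosome
  for (cc in unique(gm$chrom))
    expect_lte(nrow(unique(gm$haps[, gm$chrom == cc])), 3)
})

test_that("independent-sites derived counts follow the 1/k spectrum", {
  cfg <- sim_config(n_samples = 10, chrom_length = 5e6,
                    target_snp_count = 50000, seed = 9)
  gm <- simulate_neutral(cfg, "independent")
  k <- allele_counts(gm)$alt
  n_hap <- 20
  expect_true(all(k >= 1 & k <= n_hap - 1))
  expected <- (1 / seq_len(n_hap - 1)) / sum(1 / seq_len(n_hap - 1))
  obs <- tabulate(k, n_hap - 1)
  gof <- suppressWarnings(chisq.test(obs, p = expected))
  expect_gt(gof$p.value, 0.01)
})

test_that("positions are sorted, unique and in range; bad target errors", {
  cfg <- sim_config(n_samples = 4, chrom_length = 5000,
                    target_snp_count = 400, seed = 2)
  gm <- simulate_neutral(cfg, "mosaic")
  for (cc in unique(gm$chrom)) {
    p <- gm$pos[gm$chrom == cc]
    expect_false(is.unsorted(p, strictly = TRUE))
    expect_true(all(p >= 1 & p <= 5000))
  }
  expect_error(simulate_neutral(
    sim_config(n_samples = 4, chrom_length = 100, target_snp_count = 101)),
    "distinct positions")
})

test_that("inject_sweep creates monomorphism at carrier_fraction 1", {
  gm <- small_mosaic(seed = 1, n_samples = 10, chrom_length = 1e6, snps = 300)
  swept <- inject_sweep(gm, "chr1", 2e5, 6e5, 1, seed = 3)
  idx <- which(gm$pos >= 2e5 & gm$pos <= 6e5)
  expect_true(length(idx) > 10)
  expect_true(all(apply(swept$haps[, idx, drop = FALSE], 2,
                        function(a) length(unique(a)) == 1)))
  out <- which(gm$pos < 2e5 | gm$pos > 6e5)
  expect_identical(swept$haps[, out], gm$haps[, out])
  tr <- attr(swept, "sweep_truth")
  expect_identical(c(tr$start, tr$end), c(2e5, 6e5))
  expect_error(inject_sweep(gm, "chr1", 1, 10, 0.5), "no SNPs")
})

test_that("partial sweeps depress diversity inside the region", {
  hits <- 0
  for (r in 1:10) {
    gm <- small_mosaic(seed = 100 + r, n_samples = 16,
                       chrom_length = 2e6, snps = 600)
    swept <- inject_sweep(gm, "chr1", 8e5, 1.2e6, 0.8, seed = r)
    pw <- windowed_pi(swept, 1e5)
    inside <- pw$start >= 8e5 & pw$end <= 1.2e6
    if (mean(pw$pi[inside]) < mean(pw$pi)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("inject_roh homozygoses the tract and records truth", {
  gm <- small_mosaic(seed = 4, n_samples = 8, chrom_length = 1e6, snps = 400)
  out <- inject_roh(gm, "S003", "chr1", 3e5, 7e5)
  g <- geno_codes(out)["S003", ]
  idx <- gm$pos >= 3e5 & gm$pos <= 7e5
  expect_true(all(g[idx] %in% c(0L, 2L)))
  tr <- attr(out, "roh_truth")
  expect_identical(tr$sample, "S003")
  # zero-SNP region: matrix unchanged, truth still recorded
  out2 <- inject_roh(gm, "S001", "chr1", 1, 2)
  expect_identical(out2$haps, gm$haps)
  expect_identical(nrow(attr(out2, "roh_truth")), 1L)
})

test_that("inject_missing_and_errors hits target rates and is confined", {
  gm <- small_mosaic(seed = 6, n_samples = 25, chrom_length = 1e6, snps = 400)
  expect_identical(inject_missing_and_errors(gm, 0, 0)$haps, gm$haps)
  out <- inject_missing_and_errors(gm, missing_rate = 0.5, seed = 8)
  g <- geno_codes(out)
  frac <- mean(is.na(g))
  expect_gte(frac, 0.47)  # binomial bound on 10,000 genotypes
  expect_lte(frac, 0.53)
  # flips only on non-missing entries
  out2 <- inject_missing_and_errors(gm, missing_rate = 0.3,
                                    error_rate = 0.2, seed = 8)
  expect_identical(is.na(out2$haps), is.na(
    inject_missing_and_errors(gm, missing_rate = 0.3, seed = 8)$haps))
})

test_that("mosaic LD decays: binned mean r2 non-increasing on average", {
  gm <- small_mosaic(seed = 13, n_samples = 24, chrom_length = 5e6,
                     snps = 1500)
  dec <- ld_decay(gm, max_dist = 5e5, bin_width = 1e4)
  r2 <- dec$mean_r2[dec$n_pairs >= 50]
  # monotone trend: fitted slope of mean r2 on bin index is negative
  expect_lt(coef(lm(r2 ~ seq_along(r2)))[2], 0)
  expect_gt(r2[1], r2[length(r2)])
})

test_that("truth tables are written as BED and TSV", {
  gm <- small_mosaic(seed = 4, n_samples = 8, chrom_length = 1e6, snps = 300)
  gm <- inject_sweep(gm, "chr1", 2e5, 4e5, 0.9, seed = 1)
  gm <- inject_roh(gm, "S002", "chr1", 5e5, 8e5)
  sp <- withr::local_tempfile(fileext = ".bed")
  rp <- withr::local_tempfile(fileext = ".tsv")
  write_truth(gm, sp, rp)
  bed <- read.table(sp, sep = "\t")
  expect_equal(bed$V2, 2e5 - 1)  # 0-based half-open
  expect_equal(bed$V3, 4e5)
  roh <- read.table(rp, sep = "\t", header = TRUE)
  expect_identical(roh$sample, "S002")
})
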