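test_that("ehh computes pair-sharing fractions by hand-checkable cases", {
  # 6 haplotypes; core at site 2 with four '1' carriers; next site splits
  # them 2+2; the site after separates everyone.
  haps <- cbind(c(0L, 0L, 1L, 1L, 0L, 1L),
                c(1L, 1L, 1L, 1L, 0L, 0L),
                c(0L, 0L, 1L, 1L, 0L, 1L),
                c(1L, 0L, 0L, 1L, 1L, 0L))
  gm <- make_gm(haps, pos = c(100L, 200L, 300L, 400L))
  curve <- ehh(gm, 2, 1L, cutoff = 0.05)
  expect_identical(attr(curve, "K"), 4L)
  expect_equal(curve$ehh[curve$offset == 0], 1)
  # right side: split 2+2 -> (1+1)/6
  expect_equal(curve$ehh[curve$offset == 100], 2 / 6)
  # next site: carriers 1,2 split by alleles (1,0); carriers 3,4 by (0,1)
  # -> all four distinct -> EHH 0
  expect_equal(curve$ehh[curve$offset == 200], 0)
  expect_false(attr(curve, "right_truncated"))
  # monotone non-increasing away from the core on each side
  right <- curve[curve$offset >= 0, ]
  expect_true(all(diff(right$ehh[order(right$offset)]) <= 0))
})

test_that("ehh respects gaps and extension limits", {
  haps <- matrix(rep(c(1L, 1L, 0L, 0L), 5), 4, 5)
  gm <- make_gm(haps, pos = c(100L, 200L, 300L, 600300L, 600400L))
  # gap of 600 kb > max_gap 200 kb truncates the right side
  curve <- ehh(gm, 2, 1L)
  expect_true(attr(curve, "right_truncated"))
  expect_true(max(curve$offset) <= 100)
  # max_extend stops the walk
  curve2 <- ehh(gm, 1, 1L, max_extend = 150)
  expect_true(max(abs(curve2$offset)) <= 150)
})

test_that("ihh integrates trapezoids to the crossing point", {
  curve <- data.frame(offset = c(-1000, 0, 1000), ehh = c(0.05, 1, 0.05))
  attr(curve, "left_truncated") <- FALSE
  attr(curve, "right_truncated") <- FALSE
  out <- ihh(curve)
  expect_equal(out$left, (1 + 0.05) / 2 * 1000)
  expect_equal(out$right, 525)
  expect_equal(out$ihh, 1050)  # symmetric curve: total = 2 x one side
  # flat EHH of 1 over [0, L] bounds the integral below by L
  curve2 <- data.frame(offset = c(0, 500, 800, 900), ehh = c(1, 1, 1, 0.01))
  attr(curve2, "left_truncated") <- FALSE
  attr(curve2, "right_truncated") <- FALSE
  expect_gte(ihh(curve2)$right, 800)
  # truncated side voids the total
  attr(curve2, "left_truncated") <- TRUE
  expect_true(is.na(ihh(curve2)$ihh))
})

test_that("iHS sign flips when ancestral/derived labels swap", {
  gm <- small_mosaic(seed = 19, n_samples = 16, chrom_length = 8e6, snps = 1600)
  recs <- ihs_scan(gm)
  expect_gt(nrow(recs), 50)
  core <- which(gm$pos == recs$pos[25] & gm$chrom == recs$chrom[25])
  r <- ihs_unstandardized(gm, core)
  gm_flip <- gm
  gm_flip$haps <- 1L - gm_flip$haps
  r_flip <- ihs_unstandardized(gm_flip, core)
  expect_equal(r_flip$ihs_u, -r$ihs_u, tolerance = 1e-12)
  expect_equal(r_flip$ihh_a, r$ihh_d, tolerance = 1e-12)
  # scan path and per-core path agree
  expect_equal(r$ihs_u, recs$ihs_u[25], tolerance = 1e-12)
})

test_that("EHH curves from the scan are monotone non-increasing", {
  gm <- small_mosaic(seed = 29, n_samples = 10, chrom_length = 1e6, snps = 300)
  ac <- allele_counts(gm)
  cores <- which(pmin(ac$alt, ac$ref) / ac$n >= 0.2)[1:20]
  for (core in cores) {
    for (al in 0:1) {
      curve <- ehh(gm, core, al)
      left <- curve$ehh[order(curve$offset)][curve$offset <= 0]
      right <- curve$ehh[order(curve$offset)][sort(curve$offset) >= 0]
      expect_true(all(diff(right) <= 1e-12))
      expect_true(all(diff(rev(left)) <= 1e-12))
    }
  }
})

test_that("ihs_standardize z-scores within bins and merges small bins", {
  recs <- data.frame(chrom = "chr1", pos = 1:3, freq_derived = 0.52,
                     ihh_a = 1, ihh_d = 1, ihs_u = c(1, 2, 3))
  std <- ihs_standardize(recs, n_bins = 20, min_bin = 2)
  expect_equal(std$ihs_std, c(-1, 0, 1))
  # adding a constant within a bin leaves standardized scores unchanged
  recs2 <- recs; recs2$ihs_u <- recs$ihs_u + 5
  expect_equal(ihs_standardize(recs2, 20, 2)$ihs_std, std$ihs_std)

  # small bins merge with the nearest occupied neighbour
  recs3 <- data.frame(chrom = "chr1", pos = 1:30,
                      freq_derived = c(rep(0.12, 28), 0.18, 0.31),
                      ihh_a = 1, ihh_d = 1, ihs_u = rnorm(30, 0, 1) + 1:30)
  std3 <- ihs_standardize(recs3, n_bins = 20, min_bin = 5)
  expect_identical(length(unique(std3$bin)), 1L)
  expect_equal(mean(std3$ihs_std), 0, tolerance = 1e-10)
  expect_equal(sd(std3$ihs_std), 1, tolerance = 1e-10)
  # degenerate bin errors
  recs4 <- recs; recs4$ihs_u <- c(1, 1, 1)
  expect_error(ihs_standardize(recs4, 20, 2), "zero iHS variance")
})

test_that("windowed_abs_ihs averages |iHS| on the shared window grid", {
  gm <- make_gm(matrix(rep(c(1L, 0L), 6), 4, 3),
                pos = c(100L, 150L, 250000L),
                chrom_lengths = c(chr1 = 4e5))
  recs <- data.frame(chrom = "chr1", pos = c(100L, 150L, 250000L),
                     freq_derived = 0.5, ihh_a = 1, ihh_d = 1,
                     ihs_u = 0, bin = 1L, ihs_std = c(-2, 1, 3))
  w <- windowed_abs_ihs(recs, gm, 1e5)
  expect_identical(nrow(w), 4L)           # grid extends to chrom length
  expect_equal(w$mean_abs_ihs[1], 1.5)    # (2 + 1)/2
  expect_true(is.na(w$mean_abs_ihs[2]))
  expect_equal(w$mean_abs_ihs[3], 3)
  expect_identical(w$n_scored, c(2L, 0L, 1L, 0L))
})
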