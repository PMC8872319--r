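# Small builders and independent brute-force oracles used across the suite.

# Genotype matrix from a haplotype matrix (2S x V) with minimal metadata.
make_gm <- function(haps, pos = NULL, chrom = NULL, phased = TRUE,
                    chrom_lengths = NULL) {
  haps <- as.matrix(haps)
  v <- ncol(haps)
  s <- nrow(haps) / 2
  if (is.null(pos)) pos <- as.integer(seq_len(v) * 100L)
  if (is.null(chrom)) chrom <- rep("chr1", v)
  genotype_matrix(haps, chrom, pos, rep("A", v), rep("G", v),
                  sprintf("S%02d", seq_len(s)), phased, chrom_lengths)
}

# Random phased matrix; missingness applied per genotype (both haplotypes).
random_gm <- function(s, v, seed, miss = 0) {
  set.seed(seed)
  haps <- matrix(rbinom(2 * s * v, 1, runif(1, 0.2, 0.8)), 2 * s, v)
  if (miss > 0) {
    m <- matrix(runif(s * v) < miss, s, v)
    odd <- seq(1, 2 * s, by = 2)
    haps[odd, ][m] <- NA
    haps[odd + 1, ][m] <- NA
  }
  make_gm(haps)
}

# Oracle: per-site diversity by direct enumeration of haplotype pairs.
oracle_site_pi <- function(alleles) {
  a <- alleles[!is.na(alleles)]
  n <- length(a)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) diff <- diff + (a[i] != a[j])
  diff / (n * (n - 1) / 2)
}

# Oracle: windowed pi as brute-force mean pairwise haplotype differences
# per window divided by window length (complete data).
oracle_windowed_pi <- function(haps, pos, window_size) {
  wi <- (pos - 1) %/% window_size
  vapply(sort(unique(wi)), function(w) {
    cols <- which(wi == w)
    tot <- 0; n <- nrow(haps)
    for (i in seq_len(n - 1))
      for (j in seq(i + 1, n))
        tot <- tot + sum(haps[i, cols] != haps[j, cols])
    tot / (n * (n - 1) / 2) / window_size
  }, 0)
}

# Oracle: r2 as the squared Pearson correlation of the two 0/1 haplotype
# vectors (pairwise-complete) — an independent route to the D-based formula.
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  unname(stats::cor(x, y)^2)
}

# Oracle: exact HWE p-value by full enumeration of genotype configurations
# (nAA, nAa, naa) with the observed allele total, weighted by the Levene
# multinomial kernel n!/(nAA! nAa! naa!) * 2^nAa.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_alt <- 2 * n_aa + n_Aa
  cfg <- expand.grid(aa = 0:n, het = 0:n)
  cfg <- cfg[cfg$aa + cfg$het <= n & 2 * cfg$aa + cfg$het == n_alt, ]
  w <- exp(lfactorial(n) - lfactorial(cfg$aa) - lfactorial(cfg$het) -
             lfactorial(n - cfg$aa - cfg$het) + cfg$het * log(2))
  p <- w / sum(w)
  obs <- p[cfg$het == n_Aa]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Oracle: maximal homozygous streaks via rle (no tolerated het/missing),
# for comparison with detect_roh under max_opposite = 0, max_missing = 0.
oracle_hom_runs <- function(g, pos, min_snp, min_len) {
  hom <- !is.na(g) & g != 1
  r <- rle(hom)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_snp
  out <- data.frame(start = pos[starts[keep]], end = pos[ends[keep]],
                    n_snps = r$lengths[keep])
  out$length <- out$end - out$start + 1
  out[out$length >= min_len, , drop = FALSE]
}

# Small neutral mosaic dataset reused by several tests.
small_mosaic <- function(seed = 11, n_samples = 24, chrom_length = 5e6,
                         snps = 1200, n_chromosomes = 1) {
  simulate_neutral(sim_config(n_samples = n_samples,
                              n_chromosomes = n_chromosomes,
                              chrom_length = chrom_length,
                              target_snp_count = snps, seed = seed),
                   "mosaic")
}
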