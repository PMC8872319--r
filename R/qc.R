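#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts: conditional on the observed
#' minor-allele count, the number of heterozygotes follows the Levene-Haldane
#' distribution; the p-value is the total probability of all heterozygote
#' configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers).
#' @return the exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one individual required")
  rare <- 2L * min(n_AA, n_aa) + n_Aa     # minor-allele count
  if (rare == 0L) return(1)
  # attainable heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  # log Levene-Haldane probabilities, conditional on rare count
  logp <- vapply(hets, function(h) {
    r_hom <- (rare - h) %/% 2L
    c_hom <- n - h - r_hom
    lfactorial(n) - lfactorial(r_hom) - lfactorial(h) - lfactorial(c_hom) +
      h * log(2)
  }, 0)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  obs <- p[hets == n_Aa]
  if (!length(obs)) stop("heterozygote count inconsistent with allele total")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Filter variants on call rate, MAF and Hardy-Weinberg equilibrium
#'
#' Removes variants with call rate below `call_rate_min`, minor allele
#' frequency below `maf_min` (over non-missing alleles), or exact HWE p-value
#' below `hwe_p_min`. All thresholds are strict ("remove if less than").
#' Removal is attributed to the first failing criterion in the order
#' call rate, MAF, HWE.
#'
#' @param gm a [genotype_matrix()]
#' @param maf_min,call_rate_min,hwe_p_min removal thresholds.
#' @return the filtered `genotype_matrix`, with a `filter_report` attribute:
#'   a one-row data frame of counts (`input`, `removed_call_rate`,
#'   `removed_maf`, `removed_hwe`, `retained`). The counts are mutually
#'   exclusive and sum to the input count.
#' @export
filter_variants <- function(gm, maf_min = 0.05, call_rate_min = 0.90,
                            hwe_p_min = 1e-4) {
  v <- n_variants(gm)
  s <- n_samples(gm)
  g <- geno_codes(gm)
  called <- colSums(!is.na(g))
  cr <- called / s
  ac <- allele_counts(gm)
  af <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
  maf <- pmin(af, 1 - af)

  fail_cr <- cr < call_rate_min
  fail_maf <- !fail_cr & (is.na(maf) | maf < maf_min)
  need_hwe <- !fail_cr & !fail_maf
  hwe_p <- rep(NA_real_, v)
  if (any(need_hwe)) {
    n_aa <- colSums(g == 2L, na.rm = TRUE)
    n_het <- colSums(g == 1L, na.rm = TRUE)
    n_AA <- called - n_aa - n_het
    hwe_p[need_hwe] <- vapply(which(need_hwe), function(j)
      hwe_exact_test(n_AA[j], n_het[j], n_aa[j]), 0)
  }
  fail_hwe <- need_hwe & hwe_p < hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)

  report <- data.frame(input = v,
                       removed_call_rate = sum(fail_cr),
                       removed_maf = sum(fail_maf),
                       removed_hwe = sum(fail_hwe),
                       retained = sum(keep))
  if (!any(keep)) warning("all variants removed by QC filters")
  out <- subset_variants(gm, keep)
  attr(out, "filter_report") <- report
  out
}
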