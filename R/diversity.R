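#' Per-site nucleotide diversity
#'
#' Proportion of haplotype pairs that differ at a site:
#' `ref*alt / choose(n, 2)` over the `n = ref + alt` non-missing alleles.
#'
#' @param ref_count,alt_count non-missing REF/ALT allele counts (vectorised).
#' @return per-site diversity; `NA` where fewer than 2 alleles are observed.
#' @export
site_pi <- function(ref_count, alt_count) {
  n <- ref_count + alt_count
  out <- ifelse(n >= 2, ref_count * alt_count / (n * (n - 1) / 2), NA_real_)
  as.numeric(out)
}

#' Windowed nucleotide diversity
#'
#' Non-overlapping windows tile each chromosome from position 1; the SNP at
#' 1-based position p belongs to window `floor((p-1)/window_size)`. Window pi
#' is the sum of per-site diversities divided by the window length (the
#' VCFtools "window-pi" convention). Windows without SNPs are reported with
#' pi = 0 and flagged empty.
#'
#' @param gm a [genotype_matrix()]
#' @param window_size window length in bp.
#' @return data frame: chrom, start, end, n_snps, pi, empty.
#' @export
windowed_pi <- function(gm, window_size = 1e5) {
  stopifnot(window_size >= 1)
  ac <- allele_counts(gm)
  sp <- site_pi(ac$ref, ac$alt)
  sp[is.na(sp)] <- 0
  out <- lapply(unique(gm$chrom), function(cc) {
    sel <- gm$chrom == cc
    n_win <- n_windows_for(gm, cc, window_size)
    wi <- window_index(gm$pos[sel], window_size) + 1L
    n_snps <- tabulate(wi, nbins = n_win)
    # positions are sorted, so window indices appear in increasing order
    pi <- numeric(n_win)
    pi[unique(wi)] <- as.numeric(rowsum(sp[sel], wi, reorder = FALSE))
    cbind(data.frame(chrom = cc), window_coords(n_win, window_size),
          data.frame(n_snps = n_snps, pi = pi / window_size,
                     empty = n_snps == 0L))
  })
  do.call(rbind, out)
}

#' Tajima (1989) normalization constants
#'
#' @param n haplotype count (>= 4).
#' @return list with n, a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 4) stop("Tajima's D requires at least 4 haplotypes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' Per window, S is the count of segregating sites and pi-hat the sum of
#' per-site mean pairwise differences (not divided by window length);
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`. Sites use pairwise-complete
#' allele counts; the normalization constants use the full haplotype count
#' `2 * n_samples`. Windows with S = 0 are reported `NA`.
#'
#' @param gm a [genotype_matrix()]
#' @param window_size window length in bp.
#' @return data frame: chrom, start, end, n_snps, S, tajima_d.
#' @export
windowed_tajima_d <- function(gm, window_size = 1e5) {
  k <- tajima_constants(2L * n_samples(gm))
  ac <- allele_counts(gm)
  sp <- site_pi(ac$ref, ac$alt)
  seg <- !is.na(sp) & sp > 0
  sp[is.na(sp)] <- 0
  out <- lapply(unique(gm$chrom), function(cc) {
    sel <- gm$chrom == cc
    n_win <- n_windows_for(gm, cc, window_size)
    wi <- window_index(gm$pos[sel], window_size) + 1L
    n_snps <- tabulate(wi, nbins = n_win)
    S <- numeric(n_win); pi_hat <- numeric(n_win)
    u <- unique(wi)  # already sorted: positions increase within chromosome
    S[u] <- as.numeric(rowsum(as.numeric(seg[sel]), wi, reorder = FALSE))
    pi_hat[u] <- as.numeric(rowsum(sp[sel], wi, reorder = FALSE))
    d <- ifelse(S > 0,
                (pi_hat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1)),
                NA_real_)
    cbind(data.frame(chrom = cc), window_coords(n_win, window_size),
          data.frame(n_snps = n_snps, S = S, tajima_d = d))
  })
  do.call(rbind, out)
}
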