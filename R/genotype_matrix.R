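#' Phased biallelic genotype matrix
#'
#' The central container of the package: phased (or unphased) biallelic SNP
#' genotypes for `S` diploid samples at `V` variants, stored as a haplotype
#' matrix with `2*S` rows (sample `i` owns rows `2i-1` and `2i`) and `V`
#' columns. Allele codes are `0` (REF) and `1` (ALT); missing genotypes have
#' both haplotype entries `NA`.
#'
#' @param haps integer matrix, `2*S x V`, entries in `{0L, 1L, NA}`; missing
#'   entries must come in sample pairs (both haplotypes `NA`).
#' @param chrom character vector of length `V`; variants of one chromosome
#'   must be contiguous.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt single-base REF/ALT alleles per variant.
#' @param samples sample identifiers (length `S`).
#' @param phased logical flag: `TRUE` when haplotype order within a sample is
#'   meaningful (required by [haplotype_r2()] and the EHH/iHS functions).
#' @param chrom_lengths optional named vector of chromosome lengths in bp.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(haps, chrom, pos, ref, alt, samples,
                            phased = TRUE, chrom_lengths = NULL) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  v <- ncol(haps)
  stopifnot(nrow(haps) %% 2 == 0,
            length(chrom) == v, length(pos) == v,
            length(ref) == v, length(alt) == v,
            length(samples) == nrow(haps) / 2)
  if (v > 0) {
    ok <- haps %in% c(0L, 1L, NA)
    if (!all(ok)) stop("allele codes must be 0, 1 or NA (biallelic only)")
    odd <- seq(1L, nrow(haps), by = 2L)
    if (!identical(is.na(haps[odd, , drop = FALSE]),
                   is.na(haps[odd + 1L, , drop = FALSE])))
      stop("missing genotypes must mask both haplotypes of a sample")
    if (anyDuplicated(rle(as.character(chrom))$values))
      stop("variants of one chromosome must be contiguous")
    for (cc in unique(chrom)) {
      p <- pos[chrom == cc]
      if (is.unsorted(p, strictly = TRUE))
        stop("positions must be strictly increasing within chromosome ", cc)
    }
  }
  structure(list(haps = haps,
                 chrom = as.character(chrom),
                 pos = as.integer(pos),
                 ref = as.character(ref),
                 alt = as.character(alt),
                 samples = as.character(samples),
                 phased = isTRUE(phased),
                 chrom_lengths = chrom_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s), %d chromosome(s)\n",
              n_samples(x), n_variants(x),
              if (x$phased) "phased" else "unphased",
              length(unique(x$chrom))))
  miss <- mean(is.na(x$haps))
  cat(sprintf("  missing haplotype entries: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / variants
#' @param gm a [genotype_matrix()]
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_variants <- function(gm) length(gm$pos)

#' Per-variant allele counts
#'
#' @param gm a [genotype_matrix()]
#' @return `allele_counts()`: a list with `ref`, `alt` (counts among
#'   non-missing haplotypes) and `n` (non-missing haplotype count) per variant.
#' @export
allele_counts <- function(gm) {
  alt <- colSums(gm$haps == 1L, na.rm = TRUE)
  n <- colSums(!is.na(gm$haps))
  list(ref = n - alt, alt = alt, n = n)
}

#' Diploid genotype codes
#'
#' @param gm a [genotype_matrix()]
#' @return `S x V` integer matrix of ALT-allele dosages (0/1/2, `NA` missing).
#' @export
geno_codes <- function(gm) {
  odd <- seq(1L, nrow(gm$haps), by = 2L)
  g <- gm$haps[odd, , drop = FALSE] + gm$haps[odd + 1L, , drop = FALSE]
  rownames(g) <- gm$samples
  g
}

#' Subset a genotype matrix by variant index
#' @param gm a [genotype_matrix()]
#' @param idx integer or logical variant index.
#' @return a new `genotype_matrix`.
#' @export
subset_variants <- function(gm, idx) {
  genotype_matrix(gm$haps[, idx, drop = FALSE],
                  gm$chrom[idx], gm$pos[idx], gm$ref[idx], gm$alt[idx],
                  gm$samples, gm$phased, gm$chrom_lengths)
}

# Non-overlapping windows anchored at position 1: a SNP at 1-based position p
# falls in window index (p - 1) %/% window_size.
window_index <- function(pos, window_size) (pos - 1L) %/% as.integer(window_size)

# Full tiling of window start/end coordinates for one chromosome, covering
# windows 0..n_win-1 (1-based inclusive coordinates).
window_coords <- function(n_win, window_size) {
  idx <- seq_len(n_win) - 1L
  data.frame(start = idx * window_size + 1, end = (idx + 1) * window_size)
}

# Number of windows needed for a chromosome: up to chrom_lengths when known,
# else up to the window containing the last SNP.
n_windows_for <- function(gm, chr, window_size) {
  len <- if (!is.null(gm$chrom_lengths) && chr %in% names(gm$chrom_lengths))
    gm$chrom_lengths[[chr]] else NULL
  if (!is.null(len) && !is.na(len)) {
    as.integer((len - 1) %/% window_size + 1)
  } else {
    p <- gm$pos[gm$chrom == chr]
    as.integer(window_index(max(p), window_size) + 1)
  }
}
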