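#' ROH detection parameters (consecutive method)
#'
#' Defaults follow the consecutive-runs convention of detectRUNS: a run needs
#' at least `min_snp` SNPs and `min_length_bps` bp, tolerates up to
#' `max_opposite` heterozygous and `max_missing` missing calls, and is broken
#' by an inter-SNP gap larger than `max_gap`.
#'
#' @param min_snp minimum SNPs per run.
#' @param min_length_bps minimum run length in bp.
#' @param max_gap maximum gap between adjacent SNPs in a run (bp).
#' @param max_opposite heterozygous calls tolerated inside a run.
#' @param max_missing missing calls tolerated inside a run.
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(min_snp = 15, min_length_bps = 1000, max_gap = 1e6,
                       max_opposite = 0, max_missing = 1) {
  stopifnot(min_snp >= 0, min_length_bps >= 0, max_gap >= 0,
            max_opposite >= 0, max_missing >= 0)
  structure(list(min_snp = min_snp, min_length_bps = min_length_bps,
                 max_gap = max_gap, max_opposite = max_opposite,
                 max_missing = max_missing), class = "roh_params")
}

# Scan one sample/chromosome. g: genotype codes (0/1/2/NA), pos sorted.
# Returns data frame of runs (start/end at first/last homozygous SNP).
roh_scan_one <- function(g, pos, params) {
  runs <- list()
  n <- length(g)
  hom <- !is.na(g) & g != 1L
  het <- !is.na(g) & g == 1L

  start_i <- NA_integer_; last_hom <- NA_integer_
  n_het <- 0L; n_miss <- 0L; n_in_run <- 0L

  emit <- function() {
    if (!is.na(start_i) && !is.na(last_hom)) {
      len <- pos[last_hom] - pos[start_i] + 1
      n_snps <- last_hom - start_i + 1L
      if (n_snps >= params$min_snp && len >= params$min_length_bps)
        runs[[length(runs) + 1L]] <<- data.frame(
          start = pos[start_i], end = pos[last_hom],
          n_snps = n_snps, length = len)
    }
  }

  i <- 1L
  while (i <= n) {
    gap_break <- !is.na(start_i) && !is.na(last_hom) &&
      (pos[i] - pos[i - 1L]) > params$max_gap
    if (gap_break) {
      emit()
      start_i <- NA_integer_; last_hom <- NA_integer_
      n_het <- 0L; n_miss <- 0L
    }
    if (hom[i]) {
      if (is.na(start_i)) start_i <- i
      last_hom <- i
    } else if (het[i]) {
      if (is.na(start_i)) {
        # heterozygote outside a run: nothing to do
      } else if (n_het + 1L > params$max_opposite) {
        emit()
        start_i <- NA_integer_; last_hom <- NA_integer_
        n_het <- 0L; n_miss <- 0L
      } else n_het <- n_het + 1L
    } else {  # missing
      if (!is.na(start_i)) {
        if (n_miss + 1L > params$max_missing) {
          emit()
          start_i <- NA_integer_; last_hom <- NA_integer_
          n_het <- 0L; n_miss <- 0L
        } else n_miss <- n_miss + 1L
      }
    }
    i <- i + 1L
  }
  emit()
  if (!length(runs))
    data.frame(start = numeric(), end = numeric(),
               n_snps = integer(), length = numeric())
  else do.call(rbind, runs)
}

#' Detect runs of homozygosity (consecutive method)
#'
#' Scans each sample and chromosome in position order, growing a candidate
#' run over homozygous calls while tolerating up to `max_opposite`
#' heterozygous and `max_missing` missing calls; a gap larger than `max_gap`
#' terminates the run. Run coordinates span the first to the last homozygous
#' SNP of the run, and runs shorter than `min_snp` SNPs or `min_length_bps`
#' bp are dropped.
#'
#' @param gm a [genotype_matrix()]
#' @param params a [roh_params()].
#' @return data frame: sample, chrom, start, end, n_snps, length
#'   (1-based inclusive; length = end - start + 1).
#' @export
detect_roh <- function(gm, params = roh_params()) {
  g <- geno_codes(gm)
  out <- list()
  for (si in seq_len(n_samples(gm))) {
    for (cc in unique(gm$chrom)) {
      sel <- gm$chrom == cc
      runs <- roh_scan_one(g[si, sel], gm$pos[sel], params)
      if (nrow(runs))
        out[[length(out) + 1L]] <- cbind(
          data.frame(sample = gm$samples[si], chrom = cc), runs)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length = numeric()))
  rownames2 <- do.call(rbind, out)
  rownames(rownames2) <- NULL
  rownames2
}

#' Genomic inbreeding from ROH (F_ROH) and ROH length classes
#'
#' `F_ROH(sample) = sum of ROH lengths / L`, where `L` is the SNP-covered
#' genome length (sum over chromosomes of last minus first SNP position + 1).
#' ROH are also binned into the length classes 0-2, 2-4, 4-8 and >8 Mb, with
#' per-class counts, percentages of all ROH, and the mean per-sample F_ROH
#' restricted to the class.
#'
#' @param rohs output of [detect_roh()].
#' @param gm the same [genotype_matrix()] the ROH were called on.
#' @return list with `per_sample` (sample, n_roh, total_length, froh),
#'   `class_summary` (class, n, pct, mean_froh) and `genome_length`.
#' @export
froh <- function(rohs, gm) {
  L <- sum(vapply(unique(gm$chrom), function(cc) {
    p <- gm$pos[gm$chrom == cc]
    max(p) - min(p) + 1
  }, 0))
  per_sample <- data.frame(sample = gm$samples, n_roh = 0L,
                           total_length = 0, froh = 0)
  breaks <- c(0, 2e6, 4e6, 8e6, Inf)
  labels <- c("0-2Mb", "2-4Mb", "4-8Mb", ">8Mb")
  class_summary <- data.frame(class = labels, n = 0L, pct = NA_real_,
                              mean_froh = 0)
  if (nrow(rohs)) {
    agg <- rowsum(cbind(n = 1, len = rohs$length), rohs$sample)
    mi <- match(rownames(agg), per_sample$sample)
    per_sample$n_roh[mi] <- agg[, "n"]
    per_sample$total_length[mi] <- agg[, "len"]
    per_sample$froh <- per_sample$total_length / L
    cls <- cut(rohs$length, breaks, labels = labels, right = FALSE)
    class_summary$n <- as.integer(table(cls))
    class_summary$pct <- 100 * class_summary$n / nrow(rohs)
    for (ci in seq_along(labels)) {
      sel <- cls == labels[ci]
      if (any(sel)) {
        by_sample <- rowsum(rohs$length[sel], rohs$sample[sel])
        fr <- numeric(n_samples(gm))
        fr[match(rownames(by_sample), gm$samples)] <- by_sample / L
        class_summary$mean_froh[ci] <- mean(fr)
      }
    }
  }
  list(per_sample = per_sample, class_summary = class_summary,
       genome_length = L)
}
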