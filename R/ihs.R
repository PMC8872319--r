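#' Extended haplotype homozygosity around a core SNP
#'
#' Restricts to haplotypes carrying `allele` at the core site and extends
#' SNP-by-SNP left and right; at each extension the carriers are partitioned
#' by their haplotype over the interval from the core to the current site,
#' and `EHH = sum_g C(k_g, 2) / C(K, 2)` over groups of size `k_g` among the
#' `K` carriers. A side stops when EHH drops below `cutoff`; it is flagged
#' truncated when `max_extend`, an inter-SNP gap larger than `max_gap`, or the
#' chromosome end is hit first. Extension sites with missing alleles among
#' carriers are skipped.
#'
#' @param gm a phased [genotype_matrix()]
#' @param core variant index of the core SNP.
#' @param allele core allele (0 = REF/ancestral, 1 = ALT/derived).
#' @param cutoff EHH stopping threshold.
#' @param max_extend maximum extension from the core (bp). The default, 3 Mb,
#'   is sized so that EHH on strong-LD panels (r2 above 0.2 out to ~200 kb)
#'   usually decays below the cutoff before the cap; cores that still hit the
#'   cap are flagged truncated and discarded by the iHS scan.
#' @param max_gap maximum tolerated inter-SNP gap (bp).
#' @return data frame (offset, ehh) including the core point (0, 1), ordered
#'   by offset; attributes `left_truncated`, `right_truncated`, `K`,
#'   `cutoff`.
#' @export
ehh <- function(gm, core, allele, cutoff = 0.05, max_extend = 3e6,
                max_gap = 2e5) {
  if (!gm$phased) stop("EHH requires phased genotypes")
  carriers <- which(!is.na(gm$haps[, core]) & gm$haps[, core] == allele)
  K <- length(carriers)
  if (K < 2) stop("fewer than 2 carriers of the core allele")
  cc <- gm$chrom[core]
  chrom_idx <- which(gm$chrom == cc)
  pos0 <- gm$pos[core]

  walk <- function(direction) {
    sites <- if (direction > 0) chrom_idx[chrom_idx > core]
             else rev(chrom_idx[chrom_idx < core])
    .ehh_walk(gm$haps, carriers, sites, as.numeric(gm$pos[sites]),
              as.numeric(pos0), cutoff, max_extend, max_gap)
  }

  left <- walk(-1L)
  right <- walk(+1L)
  curve <- data.frame(offset = c(rev(left$offs), 0, right$offs),
                      ehh = c(rev(left$vals), 1, right$vals))
  attr(curve, "left_truncated") <- left$truncated
  attr(curve, "right_truncated") <- right$truncated
  attr(curve, "K") <- K
  attr(curve, "cutoff") <- cutoff
  curve
}

#' Integrated haplotype homozygosity of an EHH curve
#'
#' Trapezoidal integral of EHH over bp offset, each side from the core out to
#' the first sampled point below the cutoff (which is included in the last
#' trapezoid), summed over both sides. A truncated side (EHH never fell below
#' the cutoff before the extension limit) yields `NA`.
#'
#' @param curve an [ehh()] curve.
#' @return list: `ihh` (total, `NA` if any side truncated), `left`, `right`,
#'   `truncated`.
#' @export
ihh <- function(curve) {
  trapz_side <- function(sel) {
    x <- abs(curve$offset[sel]); y <- curve$ehh[sel]
    o <- order(x)
    x <- x[o]; y <- y[o]
    if (length(x) < 2) return(0)
    sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  }
  left <- trapz_side(curve$offset <= 0)
  right <- trapz_side(curve$offset >= 0)
  truncated <- isTRUE(attr(curve, "left_truncated")) ||
    isTRUE(attr(curve, "right_truncated"))
  list(ihh = if (truncated) NA_real_ else left + right,
       left = left, right = right, truncated = truncated)
}

#' Unstandardized iHS at one core SNP
#'
#' `iHS_u = ln(iHH_ancestral / iHH_derived)`, with the ancestral allele taken
#' as REF (code 0). Cores whose EHH never decays below the cutoff on either
#' side (truncated), or with fewer than 2 carriers of either allele, or with
#' a zero integral, are undefined and return `NULL`.
#'
#' @inheritParams ehh
#' @return one-row data frame (chrom, pos, freq_derived, ihh_a, ihh_d, ihs_u)
#'   or `NULL` when undefined.
#' @export
ihs_unstandardized <- function(gm, core, cutoff = 0.05, max_extend = 3e6,
                               max_gap = 2e5) {
  r <- ihs_core(gm, core, cutoff, max_extend, max_gap)
  if (is.null(r)) return(NULL)
  data.frame(chrom = gm$chrom[core], pos = gm$pos[core],
             freq_derived = r[1], ihh_a = r[2], ihh_d = r[3], ihs_u = r[4])
}

# Numeric fast path shared by ihs_unstandardized() and ihs_scan():
# c(freq_derived, ihh_a, ihh_d, ihs_u) or NULL when undefined.
ihs_core <- function(gm, core, cutoff, max_extend, max_gap) {
  x <- gm$haps[, core]
  n_der <- sum(x == 1L, na.rm = TRUE)
  n_anc <- sum(x == 0L, na.rm = TRUE)
  if (n_der < 2 || n_anc < 2) return(NULL)
  chrom_idx <- which(gm$chrom == gm$chrom[core])
  pos0 <- as.numeric(gm$pos[core])
  right_sites <- chrom_idx[chrom_idx > core]
  left_sites <- rev(chrom_idx[chrom_idx < core])
  one_allele <- function(allele) {
    carriers <- which(!is.na(x) & x == allele)
    tot <- 0
    for (sites in list(left_sites, right_sites)) {
      w <- .ehh_walk(gm$haps, carriers, sites, as.numeric(gm$pos[sites]),
                     pos0, cutoff, max_extend, max_gap)
      if (w$truncated) return(NA_real_)
      xo <- c(0, abs(w$offs)); yo <- c(1, w$vals)
      tot <- tot + sum(diff(xo) * (yo[-length(yo)] + yo[-1]) / 2)
    }
    tot
  }
  ia <- one_allele(0L)
  if (!is.finite(ia) || ia <= 0) return(NULL)
  id <- one_allele(1L)
  if (!is.finite(id) || id <= 0) return(NULL)
  c(n_der / (n_der + n_anc), ia, id, log(ia / id))
}

#' Genome scan of unstandardized iHS
#'
#' Applies [ihs_unstandardized()] to every core SNP whose derived allele
#' frequency lies within `[maf, 1 - maf]`.
#'
#' @param gm a phased [genotype_matrix()]
#' @param maf minimum minor allele frequency of scored cores.
#' @inheritParams ehh
#' @return data frame of per-SNP records (see [ihs_unstandardized()]);
#'   attribute `"n_skipped"` counts qualifying cores with no defined score.
#' @export
ihs_scan <- function(gm, maf = 0.05, cutoff = 0.05, max_extend = 3e6,
                     max_gap = 2e5) {
  ac <- allele_counts(gm)
  af <- ifelse(ac$n > 0, ac$alt / ac$n, 0)
  cores <- which(pmin(af, 1 - af) >= maf & ac$n >= 4)
  vals <- matrix(NA_real_, length(cores), 4)
  for (k in seq_along(cores)) {
    r <- ihs_core(gm, cores[k], cutoff, max_extend, max_gap)
    if (!is.null(r)) vals[k, ] <- r
  }
  ok <- !is.na(vals[, 1])
  out <- data.frame(chrom = gm$chrom[cores[ok]], pos = gm$pos[cores[ok]],
                    freq_derived = vals[ok, 1], ihh_a = vals[ok, 2],
                    ihh_d = vals[ok, 3], ihs_u = vals[ok, 4])
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Records are binned by derived allele frequency into `n_bins` equal-width
#' bins over `[0, 1]`; bins holding fewer than `min_bin` records are merged
#' with the nearest occupied neighbour. Within each (merged) bin,
#' `ihs_std = (ihs_u - bin mean) / bin sd`.
#'
#' @param records output of [ihs_scan()].
#' @param n_bins number of frequency bins.
#' @param min_bin minimum records per bin before merging.
#' @return `records` with added columns `bin` and `ihs_std`.
#' @export
ihs_standardize <- function(records, n_bins = 20, min_bin = 20) {
  if (!nrow(records)) stop("no iHS records to standardize")
  bin <- pmin(pmax(ceiling(records$freq_derived * n_bins), 1L), n_bins)
  repeat {
    counts <- table(bin)
    occupied <- as.integer(names(counts))
    small <- occupied[counts < min_bin]
    if (!length(small) || length(occupied) == 1L) break
    b <- small[1]
    others <- setdiff(occupied, b)
    nearest <- others[which.min(abs(others - b))]
    bin[bin == b] <- nearest
  }
  records$bin <- bin
  records$ihs_std <- NA_real_
  for (b in unique(bin)) {
    sel <- bin == b
    if (sum(sel) < 2) stop("fewer than 2 records in an occupied bin")
    s <- stats::sd(records$ihs_u[sel])
    if (s == 0) stop("degenerate frequency bin with zero iHS variance")
    records$ihs_std[sel] <- (records$ihs_u[sel] - mean(records$ihs_u[sel])) / s
  }
  records
}

#' Per-window mean absolute standardized iHS
#'
#' Uses the same window tiling as [windowed_pi()]. Windows without scored
#' SNPs are reported `NA`.
#'
#' @param records output of [ihs_standardize()].
#' @param gm the [genotype_matrix()] the scan was run on (fixes the window
#'   grid, including trailing SNP-free windows).
#' @param window_size window length in bp.
#' @return data frame: chrom, start, end, n_scored, mean_abs_ihs.
#' @export
windowed_abs_ihs <- function(records, gm, window_size = 1e5) {
  out <- lapply(unique(gm$chrom), function(cc) {
    n_win <- n_windows_for(gm, cc, window_size)
    res <- cbind(data.frame(chrom = cc), window_coords(n_win, window_size),
                 data.frame(n_scored = 0L, mean_abs_ihs = NA_real_))
    sel <- records$chrom == cc
    if (any(sel)) {
      wi <- window_index(records$pos[sel], window_size) + 1L
      res$n_scored <- tabulate(wi, nbins = n_win)
      m <- rowsum(abs(records$ihs_std[sel]), wi)
      b <- as.integer(rownames(m))
      res$mean_abs_ihs[b] <- m / res$n_scored[b]
    }
    res
  })
  do.call(rbind, out)
}
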