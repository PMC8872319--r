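#' Simulation configuration
#'
#' Bundles the parameters of the synthetic genotype generator. Defaults
#' describe a desk-scale reduced-representation SNP panel: two dozen diploid
#' samples, a handful of founder haplotypes and a per-bp template-switch rate
#' calibrated so that mean r-squared decays below 0.2 within a few hundred kb.
#'
#' @param n_samples diploid individuals (>= 2).
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param target_snp_count SNPs per chromosome.
#' @param founder_haplotypes number of founder haplotypes K (>= 2, mosaic mode).
#' @param switch_rate per-bp probability of switching the copying template
#'   between adjacent SNPs (mosaic mode); controls LD decay.
#' @param missing_rate,genotype_error_rate rates in `[0, 1)` used by
#'   [inject_missing_and_errors()] when driven through [run_pipeline()].
#' @param seed integer seed; identical configs with identical seeds produce
#'   bit-identical datasets.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 24, n_chromosomes = 2,
                       chrom_length = 10e6, target_snp_count = 2000,
                       founder_haplotypes = 4, switch_rate = 1.5e-6,
                       missing_rate = 0, genotype_error_rate = 0,
                       seed = 1L) {
  stopifnot(n_samples >= 2, founder_haplotypes >= 2,
            missing_rate >= 0, missing_rate < 1,
            genotype_error_rate >= 0, genotype_error_rate < 1,
            n_chromosomes >= 1, chrom_length >= 1, target_snp_count >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.numeric(chrom_length),
                 target_snp_count = as.integer(target_snp_count),
                 founder_haplotypes = as.integer(founder_haplotypes),
                 switch_rate = as.numeric(switch_rate),
                 missing_rate = as.numeric(missing_rate),
                 genotype_error_rate = as.numeric(genotype_error_rate),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Draw derived-allele counts k in 1..(n_hap-1) with P(k) proportional to 1/k
# (the standard neutral site-frequency spectrum).
rsfs <- function(n_sites, n_hap) {
  k <- seq_len(n_hap - 1L)
  sample(k, n_sites, replace = TRUE, prob = 1 / k)
}

#' Simulate a neutral phased genotype dataset
#'
#' Two generation modes. In *mosaic* mode, `K` founder haplotypes carry
#' independent sites whose derived-allele count among founders follows the
#' neutral site-frequency spectrum (P(k) proportional to 1/k); each sample
#' haplotype is a mosaic copy of the founders, switching template between
#' adjacent SNPs with probability `1 - exp(-switch_rate * gap)`. This yields
#' distance-dependent linkage disequilibrium. In *independent-sites* mode each
#' site is drawn independently with derived count among the `2*n_samples`
#' sample haplotypes following the same spectrum — the calibration regime for
#' Tajima's D, where E[pi] = E[S]/a1 so the expected D numerator is zero.
#'
#' In mosaic mode REF is defined as the founder-majority allele (a defensible
#' ancestral-allele proxy for iHS); in independent-sites mode REF is the
#' ancestral allele as drawn.
#'
#' @param config a [sim_config()].
#' @param mode `"mosaic"` or `"independent"`.
#' @return a phased [genotype_matrix()] with no missing data.
#' @export
simulate_neutral <- function(config, mode = c("mosaic", "independent")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  if (config$target_snp_count > config$chrom_length)
    stop("target_snp_count exceeds the number of distinct positions")
  set.seed(config$seed)
  s <- config$n_samples
  n_hap <- 2L * s
  k_founders <- config$founder_haplotypes
  bases <- c("A", "C", "G", "T")

  per_chrom <- lapply(seq_len(config$n_chromosomes), function(cc) {
    v <- config$target_snp_count
    pos <- sort(sample.int(config$chrom_length, v, replace = FALSE))
    if (mode == "independent") {
      k <- rsfs(v, n_hap)
      haps <- matrix(0L, n_hap, v)
      for (j in seq_len(v)) haps[sample.int(n_hap, k[j]), j] <- 1L
    } else {
      k <- rsfs(v, k_founders)
      founders <- matrix(0L, k_founders, v)
      for (j in seq_len(v)) founders[sample.int(k_founders, k[j]), j] <- 1L
      # founder-majority allele becomes REF (code 0)
      flip <- colSums(founders) > k_founders / 2
      founders[, flip] <- 1L - founders[, flip]
      gap <- diff(pos)
      p_switch <- -expm1(-config$switch_rate * gap)
      haps <- matrix(0L, n_hap, v)
      for (h in seq_len(n_hap)) {
        tmpl <- integer(v)
        tmpl[1] <- sample.int(k_founders, 1L)
        if (v > 1) {
          sw <- runif(v - 1L) < p_switch
          for (j in 2:v)
            tmpl[j] <- if (sw[j - 1L]) sample.int(k_founders, 1L) else tmpl[j - 1L]
        }
        haps[h, ] <- founders[cbind(tmpl, seq_len(v))]
      }
    }
    ref <- sample(bases, v, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    list(haps = haps, pos = pos, ref = ref, alt = unname(alt))
  })

  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  haps <- do.call(cbind, lapply(per_chrom, `[[`, "haps"))
  chrom <- rep(chrom_names, each = config$target_snp_count)
  pos <- unlist(lapply(per_chrom, `[[`, "pos"))
  chrom_lengths <- stats::setNames(rep(config$chrom_length,
                                       config$n_chromosomes), chrom_names)
  genotype_matrix(haps, chrom, pos,
                  unlist(lapply(per_chrom, `[[`, "ref")),
                  unlist(lapply(per_chrom, `[[`, "alt")),
                  sprintf("S%03d", seq_len(s)),
                  phased = TRUE, chrom_lengths = chrom_lengths)
}

#' Inject a hard selective sweep
#'
#' Copies one randomly chosen donor haplotype's alleles over the region onto a
#' `carrier_fraction` share of all haplotypes (rounded down, at least 2),
#' creating locally reduced diversity, an excess of low-frequency variants and
#' a long shared haplotype — the three signal classes a sweep scan targets.
#'
#' @param gm a [genotype_matrix()]
#' @param chrom,start,end sweep region (1-based inclusive, one chromosome).
#' @param carrier_fraction fraction of haplotypes receiving the donor
#'   haplotype, in (0, 1].
#' @param seed integer seed.
#' @return the modified `genotype_matrix`; the ground-truth interval is
#'   attached as attribute `"sweep_truth"` (data frame: chrom, start, end,
#'   carrier_fraction).
#' @export
inject_sweep <- function(gm, chrom, start, end, carrier_fraction, seed = 1L) {
  stopifnot(carrier_fraction > 0, carrier_fraction <= 1, start <= end)
  idx <- which(gm$chrom == chrom & gm$pos >= start & gm$pos <= end)
  if (!length(idx)) stop("sweep region contains no SNPs")
  set.seed(seed)
  n_hap <- nrow(gm$haps)
  n_carriers <- max(2L, as.integer(floor(carrier_fraction * n_hap)))
  donor <- sample.int(n_hap, 1L)
  carriers <- sample.int(n_hap, n_carriers)
  gm$haps[carriers, idx] <- rep(gm$haps[donor, idx], each = n_carriers)
  attr(gm, "sweep_truth") <- data.frame(chrom = chrom, start = start,
                                        end = end,
                                        carrier_fraction = carrier_fraction)
  gm
}

#' Inject an autozygous (ROH) tract
#'
#' Overwrites haplotype 2 of `sample` with haplotype 1 over all SNPs in the
#' region, making every genotype there homozygous.
#'
#' @param gm a [genotype_matrix()]
#' @param sample sample identifier.
#' @param chrom,start,end tract (1-based inclusive).
#' @return the modified `genotype_matrix` with attribute `"roh_truth"`
#'   (data frame: sample, chrom, start, end). A region with zero SNPs leaves
#'   the matrix unchanged but still records the truth interval.
#' @export
inject_roh <- function(gm, sample, chrom, start, end) {
  si <- match(sample, gm$samples)
  if (is.na(si)) stop("unknown sample: ", sample)
  stopifnot(start <= end)
  idx <- which(gm$chrom == chrom & gm$pos >= start & gm$pos <= end)
  if (length(idx))
    gm$haps[2L * si, idx] <- gm$haps[2L * si - 1L, idx]
  truth <- data.frame(sample = sample, chrom = chrom,
                      start = start, end = end)
  attr(gm, "roh_truth") <- rbind(attr(gm, "roh_truth"), truth)
  gm
}

#' Inject missing genotypes and allele errors
#'
#' Each genotype is independently set missing with probability
#' `missing_rate`; each remaining haplotype allele is flipped with probability
#' `error_rate`. Reproducible under `seed`.
#'
#' @param gm a [genotype_matrix()]
#' @param missing_rate,error_rate rates in `[0, 1)`.
#' @param seed integer seed.
#' @return the modified `genotype_matrix`.
#' @export
inject_missing_and_errors <- function(gm, missing_rate = 0, error_rate = 0,
                                      seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            error_rate >= 0, error_rate < 1)
  if (missing_rate == 0 && error_rate == 0) return(gm)
  set.seed(seed)
  s <- n_samples(gm); v <- n_variants(gm)
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(s * v) < missing_rate, s, v)
    odd <- seq(1L, 2L * s, by = 2L)
    gm$haps[odd, ][miss] <- NA_integer_
    gm$haps[odd + 1L, ][miss] <- NA_integer_
  }
  if (error_rate > 0) {
    flip <- matrix(stats::runif(2L * s * v) < error_rate, 2L * s, v)
    flip[is.na(gm$haps)] <- FALSE
    gm$haps[flip] <- 1L - gm$haps[flip]
  }
  gm
}

#' Write ground-truth tables
#'
#' Sweep truth is written as BED (0-based, half-open); ROH truth as a
#' tab-separated table (sample, chrom, start, end; 1-based inclusive).
#'
#' @param gm a `genotype_matrix` carrying `sweep_truth`/`roh_truth`
#'   attributes.
#' @param sweep_path,roh_path output paths (either may be `NULL`).
#' @return invisibly, a list of paths written.
#' @export
write_truth <- function(gm, sweep_path = NULL, roh_path = NULL) {
  out <- list()
  st <- attr(gm, "sweep_truth")
  if (!is.null(sweep_path) && !is.null(st)) {
    bed <- data.frame(st$chrom, st$start - 1L, st$end, st$carrier_fraction)
    utils::write.table(bed, sweep_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out$sweep <- sweep_path
  }
  rt <- attr(gm, "roh_truth")
  if (!is.null(roh_path) && !is.null(rt)) {
    utils::write.table(rt, roh_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    out$roh <- roh_path
  }
  invisible(out)
}
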