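#' Assemble the per-window statistic table
#'
#' Joins windowed nucleotide diversity, Tajima's D and mean |iHS| on the
#' shared window grid (all three functions tile chromosomes identically).
#'
#' @param gm a phased [genotype_matrix()] (post-QC).
#' @param window_size window length in bp.
#' @param maf minimum MAF for iHS cores.
#' @param ihs_records optional precomputed standardized iHS records.
#' @return data frame: chrom, start, end, n_snps, pi, tajima_d,
#'   mean_abs_ihs.
#' @export
window_stats <- function(gm, window_size = 1e5, maf = 0.05,
                         ihs_records = NULL) {
  pi_tab <- windowed_pi(gm, window_size)
  d_tab <- windowed_tajima_d(gm, window_size)
  if (is.null(ihs_records))
    ihs_records <- ihs_standardize(ihs_scan(gm, maf = maf))
  ihs_tab <- windowed_abs_ihs(ihs_records, gm, window_size)
  stopifnot(nrow(pi_tab) == nrow(d_tab), nrow(pi_tab) == nrow(ihs_tab))
  out <- pi_tab[c("chrom", "start", "end", "n_snps")]
  out$pi <- ifelse(pi_tab$empty, NA_real_, pi_tab$pi)
  out$tajima_d <- d_tab$tajima_d
  out$mean_abs_ihs <- ihs_tab$mean_abs_ihs
  out
}

# Plain key:value config reader ('#' comments allowed). Values are parsed as
# numbers when possible.
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:=]+)[:=](.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed config line: '", lines[bad][1], "'")
  keys <- trimws(vapply(kv, `[`, "", 2))
  vals <- trimws(vapply(kv, `[`, "", 3))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}

#' Run the full sweep-scan pipeline
#'
#' Chains QC, windowed diversity statistics, the iHS scan, the DCMS composite
#' scan, LD-decay-based extension of significant windows and gene/QTL
#' annotation. Configuration is a named list or a plain `key: value` text
#' file; recognized keys (with defaults): `vcf` (input path; alternatively
#' pass a `genotype_matrix` as `gm`), `out_dir`, `maf` (0.05), `call_rate`
#' (0.90), `hwe_p` (1e-4), `window_size` (1e5), `p_threshold` (0.01),
#' `mcd_alpha` (0.75), `sample_rows` (50000), `extension` (LD decay distance
#' when omitted), `ld_max_dist` (1e6), `ld_bin_width` (1e4), `r2_threshold`
#' (0.2), `genes`/`qtl` (optional feature files), `seed` (1).
#'
#' @param config named list or path to a key:value config file.
#' @param gm optional in-memory [genotype_matrix()] (overrides `vcf`).
#' @return list with `gm` (filtered), `filter_report`, `window_stats`,
#'   `dcms`, `ld_decay`, `regions`; tables are also written under `out_dir`
#'   when it is set.
#' @export
run_pipeline <- function(config, gm = NULL) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  get <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  seed <- as.integer(get("seed", 1))

  if (is.null(gm)) {
    vcf <- get("vcf", NULL)
    if (is.null(vcf)) stop("config must name a 'vcf' input (or pass gm=)")
    gm <- read_vcf(vcf)
  }
  gm <- filter_variants(gm, maf_min = get("maf", 0.05),
                        call_rate_min = get("call_rate", 0.90),
                        hwe_p_min = get("hwe_p", 1e-4))
  report <- attr(gm, "filter_report")

  window_size <- get("window_size", 1e5)
  stats_tab <- window_stats(gm, window_size = window_size,
                            maf = get("maf", 0.05))
  dcms_tab <- dcms_scan(stats_tab, p_threshold = get("p_threshold", 0.01),
                        mcd_alpha = get("mcd_alpha", 0.75),
                        sample_rows = get("sample_rows", 50000), seed = seed)

  decay <- ld_decay(gm, max_dist = get("ld_max_dist", 1e6),
                    bin_width = get("ld_bin_width", 1e4),
                    r2_threshold = get("r2_threshold", 0.2), seed = seed)
  decay_dist <- attr(decay, "decay_distance")
  extension <- get("extension", NULL)
  if (is.null(extension)) {
    extension <- if (is.finite(decay_dist)) decay_dist else 2e5
    message("extension set to ", extension, " bp (LD decay distance)")
  }

  sig <- dcms_tab[dcms_tab$significant %in% TRUE, c("chrom", "start", "end")]
  regions <- extend_and_merge(sig, extension, gm$chrom_lengths)

  features <- NULL
  genes_path <- get("genes", NULL)
  qtl_path <- get("qtl", NULL)
  if (!is.null(genes_path))
    features <- read_features(genes_path, "gene")
  if (!is.null(qtl_path))
    features <- rbind(features, read_features(qtl_path, "QTL"))
  if (!is.null(features))
    regions <- overlap_features(regions, features)

  out_dir <- get("out_dir", NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(report, "filter_report.tsv")
    wt(dcms_tab, "window_stats.tsv")
    wt(decay, "ld_decay.tsv")
    wt(regions, "sweep_regions.tsv")
    if (nrow(sig))
      utils::write.table(
        data.frame(sig$chrom, sig$start - 1L, sig$end),
        file.path(out_dir, "significant_windows.bed"),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  list(gm = gm, filter_report = report, window_stats = dcms_tab,
       ld_decay = decay, extension = extension, regions = regions)
}
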