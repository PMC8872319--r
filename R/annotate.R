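#' Extend significant windows and merge into sweep regions
#'
#' Each window `[a, b]` becomes `[max(1, a - extension), b + extension]`
#' (ends clamped to the chromosome length when known); overlapping or
#' bookended extended intervals on the same chromosome are merged. Member
#' windows are recorded per merged region.
#'
#' @param windows data frame with `chrom`, `start`, `end` (1-based inclusive,
#'   non-overlapping, sorted) — typically the significant rows of a
#'   [dcms_scan()] table.
#' @param extension bp added on each side (e.g. the LD decay distance).
#' @param chrom_lengths optional named vector used to clamp region ends.
#' @return data frame: chrom, start, end, n_windows, windows (comma-joined
#'   `start-end` labels of member windows).
#' @export
extend_and_merge <- function(windows, extension, chrom_lengths = NULL) {
  stopifnot(extension >= 0)
  if (!nrow(windows))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      windows = character()))
  ext_start <- pmax(1, windows$start - extension)
  ext_end <- windows$end + extension
  if (!is.null(chrom_lengths)) {
    has <- windows$chrom %in% names(chrom_lengths)
    ext_end[has] <- pmin(ext_end[has], chrom_lengths[windows$chrom[has]])
  }
  gr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(ext_start, ext_end))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 1L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  lab <- paste0(windows$start, "-", windows$end)
  members <- split(lab[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits))
  data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
             start = GenomicRanges::start(merged),
             end = GenomicRanges::end(merged),
             n_windows = as.integer(lengths(members)),
             windows = vapply(members, paste, "", collapse = ","),
             row.names = NULL)
}

#' Annotate sweep regions with overlapping genes and QTL
#'
#' A feature is reported for a region iff their 1-based inclusive intervals
#' share at least one bp. Features on chromosomes absent from the regions are
#' counted and skipped with a message.
#'
#' @param regions output of [extend_and_merge()].
#' @param features data frame with `chrom`, `start`, `end`, `id`, `class`
#'   (`"gene"` or `"QTL"`), e.g. from [read_features()].
#' @return `regions` with added `genes` and `qtls` columns (comma-joined
#'   identifiers) and attribute `"n_unique_genes"`.
#' @export
overlap_features <- function(regions, features) {
  regions$genes <- ""
  regions$qtls <- ""
  attr(regions, "n_unique_genes") <- 0L
  if (!nrow(regions) || !nrow(features)) return(regions)
  unknown <- !(features$chrom %in% unique(regions$chrom))
  if (any(unknown))
    message(sum(unknown), " feature(s) on chromosomes absent from the ",
            "regions were skipped")
  features <- features[!unknown, , drop = FALSE]
  if (!nrow(features)) return(regions)
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  fg <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::findOverlaps(rg, fg)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (i in seq_len(nrow(regions))) {
    f <- features[sh[qh == i], , drop = FALSE]
    regions$genes[i] <- paste(unique(f$id[f$class == "gene"]), collapse = ",")
    regions$qtls[i] <- paste(unique(f$id[f$class == "QTL"]), collapse = ",")
  }
  hit_genes <- unique(features$id[unique(sh)][
    features$class[unique(sh)] == "gene"])
  attr(regions, "n_unique_genes") <- length(hit_genes)
  regions
}

#' Read gene/QTL features from GFF3 or BED
#'
#' GFF3 input keeps `type == "gene"` records (identifier from the `ID`,
#' `Name` or `gene_id` attribute); BED input is 0-based half-open and is
#' converted to 1-based inclusive coordinates (identifier from the name
#' column).
#'
#' @param path `.gff`/`.gff3` or `.bed` file.
#' @param class feature class label to assign (`"gene"` or `"QTL"`).
#' @return data frame: chrom, start, end, id, class.
#' @export
read_features <- function(path, class = c("gene", "QTL")) {
  class <- match.arg(class)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    id <- gr$ID
    if (is.null(id)) id <- gr$Name
    if (is.null(id)) id <- gr$gene_id
    if (is.null(id)) id <- paste0("gene_", seq_along(gr))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               id = as.character(id), class = class)
  } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    id <- if (ncol(bed) >= 4) as.character(bed[[4]])
          else paste0(class, "_", seq_len(nrow(bed)))
    data.frame(chrom = as.character(bed[[1]]), start = bed[[2]] + 1L,
               end = bed[[3]], id = id, class = class)
  } else stop("unsupported feature format (expected .gff/.gff3 or .bed): ",
              path)
}
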