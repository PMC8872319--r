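#' Read a GT-only VCF into a genotype matrix
#'
#' Loads biallelic SNP records from a VCF 4.x text file. Multiallelic records
#' (comma in ALT) and indels (REF or ALT longer than one base, or symbolic
#' alleles) are skipped and counted. `./.` and `.|.` genotypes are parsed as
#' missing. Unphased separators (`/`) are accepted, but then the phased flag
#' of the result is `FALSE`.
#'
#' @param path path to an uncompressed VCF file.
#' @return a [genotype_matrix()]; the number of skipped non-biallelic/indel
#'   records is attached as attribute `"n_skipped"`, and contig lengths from
#'   `##contig` header lines populate `chrom_lengths` when present.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || !grepl("^##fileformat=VCFv4", lines[1]))
    stop("not a VCF 4.x file (missing ##fileformat header): ", path)
  col_line <- grep("^#CHROM\t", lines)
  if (length(col_line) != 1)
    stop("malformed VCF: expected exactly one #CHROM header line")
  cols <- strsplit(lines[col_line], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10 || cols[9] != "FORMAT")
    stop("VCF has no FORMAT/sample columns (GT required)")
  samples <- cols[-(1:9)]
  s <- length(samples)

  chrom_lengths <- NULL
  contig <- regmatches(lines, regexec(
    "^##contig=<ID=([^,>]+),length=([0-9]+)", lines))
  contig <- contig[lengths(contig) == 3]
  if (length(contig)) {
    chrom_lengths <- as.numeric(vapply(contig, `[`, "", 3))
    names(chrom_lengths) <- vapply(contig, `[`, "", 2)
  }

  body <- lines[seq(col_line + 1L, length(lines))]
  body <- body[nzchar(body)]
  if (!length(body)) {
    gm <- genotype_matrix(matrix(integer(), 2 * s, 0), character(), integer(),
                          character(), character(), samples,
                          phased = TRUE, chrom_lengths = chrom_lengths)
    attr(gm, "n_skipped") <- 0L
    return(gm)
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(cols))
  if (length(bad))
    stop("malformed VCF record at line ", col_line + bad[1],
         ": expected ", length(cols), " fields, found ", nf[bad[1]])
  rec <- matrix(unlist(fields), ncol = length(cols), byrow = TRUE)

  ref <- rec[, 4]; alt <- rec[, 5]
  keep <- !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  ref <- ref[keep]; alt <- alt[keep]
  v <- nrow(rec)

  gt_idx <- vapply(strsplit(rec[, 9], ":", fixed = TRUE),
                   function(f) match("GT", f), 0L)
  if (anyNA(gt_idx))
    stop("malformed VCF record at line ",
         col_line + which(keep)[which(is.na(gt_idx))[1]], ": FORMAT lacks GT")

  haps <- matrix(NA_integer_, nrow = 2 * s, ncol = v)
  phased <- TRUE
  if (v > 0) {
    for (j in seq_len(v)) {
      gt <- rec[j, -(1:9)]
      if (gt_idx[j] != 1L)
        gt <- vapply(strsplit(gt, ":", fixed = TRUE), `[`, "", gt_idx[j])
      else
        gt <- sub(":.*$", "", gt)
      m <- regmatches(gt, regexec("^([0-9.])([|/])([0-9.])", gt))
      ok <- lengths(m) == 4
      if (!all(ok))
        stop("malformed genotype at line ", col_line + which(keep)[j],
             ": '", gt[!ok][1], "'")
      m <- matrix(unlist(m), ncol = 4, byrow = TRUE)
      a1 <- suppressWarnings(as.integer(m[, 2]))
      a2 <- suppressWarnings(as.integer(m[, 4]))
      if (any(c(a1, a2) > 1L, na.rm = TRUE))
        stop("allele index > 1 at line ", col_line + which(keep)[j],
             " in a biallelic record")
      miss <- is.na(a1) | is.na(a2)
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
      haps[seq(1L, 2 * s, by = 2L), j] <- a1
      haps[seq(2L, 2 * s, by = 2L), j] <- a2
      if (any(m[!miss, 3] == "/")) phased <- FALSE
    }
  }

  gm <- genotype_matrix(haps, rec[, 1], as.integer(rec[, 2]), ref, alt,
                        samples, phased = phased,
                        chrom_lengths = chrom_lengths)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' Writes GT-only records; phased data uses the `|` separator, unphased `/`,
#' and missing genotypes are written `./.`. Output is deterministic: the same
#' matrix always produces byte-identical files.
#'
#' @param gm a [genotype_matrix()]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  sep <- if (gm$phased) "|" else "/"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popsweep",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(gm$chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(gm$chrom_lengths),
                          as.integer(gm$chrom_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$samples),
                      collapse = "\t"))
  v <- n_variants(gm)
  if (v > 0) {
    odd <- seq(1L, nrow(gm$haps), by = 2L)
    a1 <- gm$haps[odd, , drop = FALSE]
    a2 <- gm$haps[odd + 1L, , drop = FALSE]
    gt <- matrix(paste0(a1, sep, a2), nrow = length(odd))
    gt[is.na(a1)] <- "./."
    body <- vapply(seq_len(v), function(j) {
      paste(c(gm$chrom[j], gm$pos[j], ".", gm$ref[j], gm$alt[j], ".",
              "PASS", ".", "GT", gt[, j]), collapse = "\t")
    }, "")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
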