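## BAM input: validation, full-pass mapping locations, and seeded
## reservoir subsampling of complete records.
##
## Two-track ingestion keeps memory bounded on large files: mapping
## locations (chromosome, position, strand, mapq, reference span) are
## loaded for every counted alignment, while per-base fields (SEQ,
## QUAL, CIGAR, TLEN, FLAG) are loaded only for a random subsample.

#' Default alignment inclusion filter
#'
#' Controls which alignments are counted in the mapping table and
#' eligible for subsampling. By default unmapped, secondary and
#' supplementary alignments are excluded; duplicates are retained
#' because duplication is reported as a statistic rather than removed.
#'
#' @param exclude_unmapped drop records with FLAG 0x4 set
#' @param exclude_secondary drop records with FLAG 0x100 set
#' @param exclude_supplementary drop records with FLAG 0x800 set
#' @param exclude_duplicates drop records with FLAG 0x400 set
#' @return a named list of class `bam_filter`
#' @export
bam_filter <- function(exclude_unmapped = TRUE,
                       exclude_secondary = TRUE,
                       exclude_supplementary = TRUE,
                       exclude_duplicates = FALSE) {
  structure(
    list(
      exclude_unmapped = isTRUE(exclude_unmapped),
      exclude_secondary = isTRUE(exclude_secondary),
      exclude_supplementary = isTRUE(exclude_supplementary),
      exclude_duplicates = isTRUE(exclude_duplicates)
    ),
    class = "bam_filter"
  )
}

filter_to_flag <- function(filter) {
  Rsamtools::scanBamFlag(
    isUnmappedQuery = if (filter$exclude_unmapped) FALSE else NA,
    isSecondaryAlignment = if (filter$exclude_secondary) FALSE else NA,
    isSupplementaryAlignment = if (filter$exclude_supplementary) FALSE else NA,
    isDuplicate = if (filter$exclude_duplicates) FALSE else NA
  )
}

find_bam_index <- function(path) {
  candidates <- c(
    paste0(path, ".bai"), sub("\\.bam$", ".bai", path),
    paste0(path, ".csi"), sub("\\.bam$", ".csi", path)
  )
  hits <- candidates[file.exists(candidates)]
  if (length(hits)) hits[1] else NA_character_
}

#' Validate a BAM file for digesting
#'
#' The digest requires a coordinate-sorted BAM with a BAI/CSI index
#' (random access underpins the per-chromosome pileup). Nothing about
#' the file's provenance (platform, aligner) is assumed or inspected.
#'
#' @param path path to a BAM file
#' @return an object of class `bam_header_info` with fields `path`,
#'   `sort_order` (`"coordinate"` or `"other"`), `has_index`, and
#'   `references` (data.frame of name, length)
#' @export
validate_bam <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    bd_stop("MissingFile", sprintf("BAM file not found: '%s'", path))
  }
  header <- tryCatch(
    Rsamtools::scanBamHeader(path)[[1]],
    error = function(e) bd_stop("TruncatedFile", conditionMessage(e))
  )
  hd <- header$text[["@HD"]]
  so <- if (!is.null(hd)) sub("^SO:", "", grep("^SO:", hd, value = TRUE)) else character(0)
  sort_order <- if (length(so) == 1L && so == "coordinate") "coordinate" else "other"
  index <- find_bam_index(path)
  info <- structure(
    list(
      path = path,
      sort_order = sort_order,
      has_index = !is.na(index),
      index = index,
      references = data.frame(
        name = names(header$targets),
        length = unname(as.integer(header$targets)),
        stringsAsFactors = FALSE
      )
    ),
    class = "bam_header_info"
  )
  if (sort_order != "coordinate") {
    bd_stop("NotCoordinateSorted",
            sprintf("BAM '%s' is not coordinate-sorted (header SO is '%s')",
                    path, if (length(so)) so else "absent"),
            info = info)
  }
  if (!info$has_index) {
    bd_stop("MissingIndex",
            sprintf("no BAI/CSI index found for BAM '%s'; index it first", path),
            info = info)
  }
  info
}

#' @export
print.bam_header_info <- function(x, ...) {
  cat("BAM header: ", x$path, "\n  sort order: ", x$sort_order,
      "; index: ", ifelse(x$has_index, x$index, "none"),
      "\n  references: ", nrow(x$references), "\n", sep = "")
  invisible(x)
}

#' Full-pass scan of mapping locations
#'
#' Loads chromosome, 1-based leftmost position, strand (FLAG bit 0x10),
#' mapping quality, and the CIGAR-derived reference span for every
#' alignment passing the inclusion filter. These light-weight columns
#' make the pileup exact; `minimal = TRUE` drops mapq and ref_span and
#' is only suitable for location-based statistics.
#'
#' @param path BAM file path (validated)
#' @param filter a [bam_filter()] configuration
#' @param minimal drop the mapq and ref_span columns
#' @return a `mapping_table`: data.frame with columns chrom (factor in
#'   reference order), pos, strand ("+"/"-"), mapq, ref_span, sorted by
#'   (chrom, pos); attributes `references`, `total_alignments`,
#'   `filtered_out`
#' @export
scan_mapping_locations <- function(path, filter = bam_filter(), minimal = FALSE) {
  info <- validate_bam(path)
  param <- Rsamtools::ScanBamParam(
    flag = filter_to_flag(filter),
    what = c("rname", "pos", "flag", "mapq", "cigar")
  )
  res <- tryCatch(
    Rsamtools::scanBam(path, param = param)[[1]],
    error = function(e) bd_stop("TruncatedFile", conditionMessage(e))
  )
  total <- Rsamtools::countBam(
    path,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(), what = character(0))
  )$records
  tab <- data.frame(
    chrom = factor(as.character(res$rname), levels = info$references$name),
    pos = res$pos,
    strand = ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+"),
    stringsAsFactors = FALSE
  )
  if (!minimal) {
    tab$mapq <- res$mapq
    tab$ref_span <- if (nrow(tab)) cigar_ref_span(res$cigar) else integer(0)
  }
  ord <- order(as.integer(tab$chrom), tab$pos)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            class = c("mapping_table", "data.frame"),
            references = info$references,
            total_alignments = total,
            filtered_out = total - nrow(tab))
}

## Columns loaded for sampled records: every SAM field the per-base
## statistics need.
SAMPLE_WHAT <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "isize", "seq", "qual")

chunk_to_records <- function(res) {
  data.frame(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    tlen = res$isize,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    stringsAsFactors = FALSE
  )
}

#' Draw a seeded uniform subsample of complete alignment records
#'
#' Single-pass reservoir sampling (Algorithm R, vectorized per chunk)
#' over all filter-passing alignments: every passing read has inclusion
#' probability `min(1, n / total)`, without replacement, and the result
#' is byte-identical for identical (path, filter, seed, n).
#'
#' @param path BAM file path (validated)
#' @param n requested sample size (default 1e5; samples of this size
#'   reproduce global per-base statistics closely, see the convergence
#'   module)
#' @param seed integer seed; the default 17 makes repeated digests of
#'   the same file identical
#' @param filter a [bam_filter()] configuration
#' @param yield_size records per chunk during the streaming pass
#' @return a `read_sample`: list with `records` (data.frame of qname,
#'   flag, chrom, pos, mapq, cigar, tlen, seq, qual), `requested_n`,
#'   `total_seen`, `seed`
#' @export
sample_full_records <- function(path, n = 1e5, seed = 17L,
                                filter = bam_filter(),
                                yield_size = 200000L) {
  stopifnot(is_scalar_number(n), n >= 1)
  n <- as.integer(n)
  info <- validate_bam(path)
  param <- Rsamtools::ScanBamParam(flag = filter_to_flag(filter),
                                   what = SAMPLE_WHAT)
  bf <- Rsamtools::BamFile(path, yieldSize = as.integer(yield_size))
  open(bf)
  on.exit(close(bf))

  reservoir <- NULL   # data.frame of up to n rows
  seen <- 0L
  with_seed(seed, {
    repeat {
      res <- tryCatch(
        Rsamtools::scanBam(bf, param = param)[[1]],
        error = function(e) bd_stop("TruncatedFile", conditionMessage(e))
      )
      m <- length(res$pos)
      if (m == 0L) break
      chunk <- chunk_to_records(res)
      idx_global <- seen + seq_len(m)
      if (seen < n) {
        take <- min(n - seen, m)
        reservoir <- rbind(reservoir, chunk[seq_len(take), , drop = FALSE])
        rest <- if (take < m) (take + 1L):m else integer(0)
      } else {
        rest <- seq_len(m)
      }
      if (length(rest)) {
        t_i <- idx_global[rest]
        keep <- stats::runif(length(rest)) < n / t_i
        if (any(keep)) {
          slots <- sample.int(n, sum(keep), replace = TRUE)
          ## later duplicates of a slot win, matching sequential
          ## Algorithm R semantics
          reservoir[slots, ] <- chunk[rest[keep], , drop = FALSE]
        }
      }
      seen <- seen + m
    }
  })
  if (seen == 0L) {
    bd_stop("NoReadsPass",
            sprintf("no alignments in '%s' pass the inclusion filter", path))
  }
  rownames(reservoir) <- NULL
  structure(
    list(records = reservoir, requested_n = n, total_seen = seen,
         seed = as.integer(seed), references = info$references),
    class = "read_sample"
  )
}

#' @export
print.read_sample <- function(x, ...) {
  cat("Read sample: ", nrow(x$records), " of ", x$total_seen,
      " passing alignments (requested ", x$requested_n,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
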