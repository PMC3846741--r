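## Mapping statistics: FLAG tabulation, mapping-quality thresholds,
## CIGAR-class mismatch fractions, duplicate-location histogram, and
## paired-end insert sizes.

FLAG_BITS <- c(
  paired = 1L, properly_paired = 2L, unmapped = 4L, mate_unmapped = 8L,
  reverse_strand = 16L, mate_reverse_strand = 32L, first_in_pair = 64L,
  second_in_pair = 128L, secondary = 256L, duplicate = 1024L,
  supplementary = 2048L
)

#' Tabulate SAM FLAG categories
#'
#' Decodes the FLAG bit field into named category counts. Categories
#' are not mutually exclusive. Applied to a file path the tabulation
#' sees every record, regardless of any inclusion filter.
#'
#' @param x a `read_sample`, an integer vector of FLAG values, or a
#'   BAM file path (all records are scanned)
#' @return named numeric vector: total, mapped, plus one count per
#'   FLAG bit category
#' @export
flag_summary <- function(x) {
  flags <- if (inherits(x, "read_sample")) {
    x$records$flag
  } else if (is.numeric(x)) {
    as.integer(x)
  } else if (is.character(x) && length(x) == 1L) {
    param <- Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag(),
                                     what = "flag")
    Rsamtools::scanBam(x, param = param)[[1]]$flag
  } else {
    stop("flag_summary() expects a read_sample, FLAG vector, or BAM path")
  }
  counts <- vapply(FLAG_BITS, function(b) sum(bitwAnd(flags, b) > 0L), numeric(1))
  c(total = length(flags), mapped = length(flags) - unname(counts["unmapped"]),
    counts)
}

#' Mapping-quality thresholds and histogram
#'
#' @param table a `mapping_table` (or anything with a `mapq` column)
#' @param cutoffs mapq cutoffs for the threshold table
#' @return list with `thresholds` (data.frame cutoff, fraction),
#'   `histogram` (data.frame mapq, count), `mean_mapq`
#' @export
mapq_summary <- function(table, cutoffs = c(1L, 10L, 20L, 30L, 60L, 70L)) {
  mapq <- table$mapq
  mapq <- mapq[!is.na(mapq)]
  n <- length(mapq)
  tab <- table(mapq)
  list(
    thresholds = data.frame(
      cutoff = cutoffs,
      fraction = vapply(cutoffs, function(cv) if (n) sum(mapq >= cv) / n else NA_real_,
                        numeric(1))
    ),
    histogram = data.frame(
      mapq = as.integer(names(tab)),
      count = as.integer(tab)
    ),
    mean_mapq = if (n) mean(mapq) else NA_real_
  )
}

#' CIGAR-class mismatch summary
#'
#' Fractions of read bases in each CIGAR class over the sampled reads:
#' M (aligned), I (inserted) and S (soft-clipped) bases are normalized
#' by total read bases; D (deleted) bases consume no read bases and
#' are normalized by total aligned reference span. Also reports the
#' fraction of reads containing any I, D or S operation.
#'
#' @param sample a `read_sample`
#' @return list with `base_fractions` (named: M, I, D, S),
#'   `reads_with_indel_or_clip` (fraction), `total_read_bases`,
#'   `total_ref_span`
#' @export
mismatch_summary <- function(sample) {
  cig <- sample$records$cigar
  if (is.null(cig) || !length(cig)) {
    bd_stop("MalformedCigar", "sample carries no CIGAR strings")
  }
  tab <- cigar_table(cig)
  total_read <- sum(as.numeric(tab[, "read_len"]))
  total_ref <- sum(as.numeric(tab[, "ref_span"]))
  any_ids <- rowSums(tab[, c("I", "D", "S"), drop = FALSE]) > 0L
  list(
    base_fractions = c(
      M = sum(as.numeric(tab[, "M"])) / total_read,
      I = sum(as.numeric(tab[, "I"])) / total_read,
      D = sum(as.numeric(tab[, "D"])) / total_ref,
      S = sum(as.numeric(tab[, "S"])) / total_read
    ),
    reads_with_indel_or_clip = mean(any_ids),
    total_read_bases = total_read,
    total_ref_span = total_ref
  )
}

#' Duplicate-mapping histogram
#'
#' Locations are keyed by (chromosome, leftmost position, strand); the
#' histogram maps the number of reads sharing a location (k) to the
#' number of such locations. PCR duplicates inflate the k >= 2 tail.
#'
#' @param table a `mapping_table`
#' @return data.frame with columns multiplicity, locations; satisfies
#'   sum(multiplicity * locations) == nrow(table)
#' @export
duplication_histogram <- function(table) {
  if (!nrow(table)) {
    return(data.frame(multiplicity = integer(0), locations = integer(0)))
  }
  key <- paste(table$chrom, table$pos, table$strand, sep = "\r")
  per_loc <- table(key)
  h <- table(as.integer(per_loc))
  data.frame(
    multiplicity = as.integer(names(h)),
    locations = as.integer(h)
  )
}

#' Insert-size distribution for paired-end data
#'
#' Insert (template) size is the distance between the outer mapped
#' ends of a read pair — the sequenced fragment length. Computed from
#' |TLEN| of properly-paired, first-in-pair records with
#' 0 < |TLEN| <= max_abs; the cap excludes translocation-scale
#' artifacts (their count is reported).
#'
#' @param sample a `read_sample`
#' @param max_abs maximum |TLEN| admitted to the histogram
#' @return list with `absent` flag; when present also `histogram`
#'   (data.frame insert_size, count), `mean`, `median`, `n_pairs`,
#'   `n_excluded`
#' @export
insert_size_summary <- function(sample, max_abs = 10000L) {
  rec <- sample$records
  proper_first <- bitwAnd(rec$flag, 2L) > 0L & bitwAnd(rec$flag, 64L) > 0L
  tlen <- abs(rec$tlen[proper_first])
  tlen <- tlen[!is.na(tlen) & tlen > 0L]
  excluded <- sum(tlen > max_abs)
  tlen <- tlen[tlen <= max_abs]
  if (!length(tlen)) {
    return(list(absent = TRUE))
  }
  h <- table(tlen)
  list(
    absent = FALSE,
    histogram = data.frame(
      insert_size = as.integer(names(h)),
      count = as.integer(h)
    ),
    mean = mean(tlen),
    median = stats::median(tlen),
    n_pairs = length(tlen),
    n_excluded = excluded
  )
}
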