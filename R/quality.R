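## Base-quality profiling from the read subsample.
##
## Quality scores are Phred-33: Q relates to the base-call error
## probability as p = 10^(-Q/10), so Q30 means p = 0.001. Positional
## statistics are computed in sequencing orientation: reverse-strand
## alignments store SEQ/QUAL reference-forward, so their QUAL is
## reversed back before position is assigned.

## Decode all QUAL strings of a sample into flat (score, position)
## vectors in sequencing orientation. Shared by the global and
## positional summaries.
sample_qual_scores <- function(sample) {
  rec <- sample$records
  quals <- rec$qual
  ok <- !is.na(quals) & quals != "*"
  if (!any(ok)) {
    bd_stop("MissingQuality", "no sampled record carries quality scores")
  }
  quals <- quals[ok]
  rev_strand <- bitwAnd(rec$flag[ok], 16L) > 0L
  lens <- nchar(quals)
  codes <- utf8ToInt(paste(quals, collapse = "")) - 33L
  pos <- sequence(lens)
  ## reverse positions for reverse-strand reads: last stored base was
  ## sequenced first
  if (any(rev_strand)) {
    flip <- rep(rev_strand, lens)
    len_rep <- rep(lens, lens)
    pos[flip] <- len_rep[flip] - pos[flip] + 1L
  }
  list(score = codes, pos = pos, read_len = lens)
}

#' Global base-quality summary
#'
#' Histogram of single-base Phred scores over the sampled reads, with
#' the fraction of bases meeting each quality cutoff and the error
#' probability p = 10^(-Q/10) annotated per score.
#'
#' @param sample a `read_sample`
#' @param cutoffs quality cutoffs for the threshold table (default
#'   10, 20, 30, 40)
#' @return list with `histogram` (data.frame score, count,
#'   error_prob), `thresholds` (data.frame cutoff, fraction),
#'   `mean_quality`, `median_quality`, `total_bases`
#' @export
quality_summary <- function(sample, cutoffs = c(10L, 20L, 30L, 40L)) {
  qs <- sample_qual_scores(sample)
  counts <- tabulate(qs$score + 1L, nbins = 94L)  # scores 0..93
  scores <- which(counts > 0) - 1L
  n <- length(qs$score)
  hist <- data.frame(
    score = scores,
    count = counts[scores + 1L],
    error_prob = 10^(-scores / 10)
  )
  thresholds <- data.frame(
    cutoff = cutoffs,
    fraction = vapply(cutoffs, function(cv) sum(counts[(cv + 1L):94L]) / n,
                      numeric(1))
  )
  list(
    histogram = hist,
    thresholds = thresholds,
    mean_quality = sum(hist$score * hist$count) / n,
    median_quality = weighted_median(hist$score, hist$count),
    total_bases = n
  )
}

#' Position-specific base-quality profile
#'
#' Score histogram, median and mean per read position (1-based, in
#' sequencing orientation). Positions beyond a read's length do not
#' contribute to that position's denominator, so mixed read lengths
#' are handled exactly.
#'
#' @param sample a `read_sample`
#' @return list with `matrix` (score x position count matrix),
#'   `median` and `mean` (numeric per position), `n_reads` (reads
#'   covering each position)
#' @export
positional_quality <- function(sample) {
  qs <- sample_qual_scores(sample)
  max_pos <- max(qs$read_len)
  max_score <- max(qs$score)
  ## 2-D tabulation: cell index = score * n_pos + pos
  cell <- qs$score * max_pos + qs$pos
  counts <- tabulate(cell, nbins = (max_score + 1L) * max_pos)
  mat <- matrix(counts, nrow = max_score + 1L, ncol = max_pos, byrow = TRUE,
                dimnames = list(score = 0:max_score, position = 1:max_pos))
  col_n <- colSums(mat)
  means <- unname(as.numeric((0:max_score) %*% mat) / col_n)
  medians <- vapply(seq_len(max_pos), function(j) {
    weighted_median(0:max_score, mat[, j])
  }, numeric(1))
  list(matrix = mat, median = medians, mean = means, n_reads = unname(col_n))
}
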