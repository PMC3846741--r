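## Sequencing-depth pileup and coverage summaries.
##
## Depth at a reference position is the number of counted alignments
## whose reference span covers it. The pileup is exact: each alignment
## contributes its CIGAR-derived reference span, accumulated with a
## difference array (O(reads + genome) per chromosome), so the global
## conservation law sum(depth) == sum(ref_span) holds on every run.

#' Exact per-base sequencing depth from a mapping table
#'
#' @param table a `mapping_table` from [scan_mapping_locations()]
#' @param meta a `genome_meta` object; chromosome lengths must cover
#'   every mapped position
#' @param bin_width width (bp) of the binned low-resolution landscape;
#'   `NULL` (default) picks chromosome length / 500 floored to a
#'   multiple of 1,000 bp, minimum 1,000 bp
#' @return a `depth_profile`: list with `depth` (named list of
#'   per-chromosome integer vectors), `landscape` (data.frame chrom,
#'   bin_start, bin_end, mean_depth), `bin_width`, `total_depth`,
#'   `genome_length`
#' @export
compute_depth <- function(table, meta, bin_width = NULL) {
  stopifnot(inherits(meta, "genome_meta"))
  if (!"ref_span" %in% names(table)) {
    bd_stop("PositionBeyondChromosome",
            "minimal mapping tables (no ref_span) cannot drive an exact pileup")
  }
  lens <- unlist(meta$chrom_lengths)
  depth <- lapply(names(lens), function(ch) integer(lens[[ch]]))
  names(depth) <- names(lens)

  if (nrow(table)) {
    by_chrom <- split(seq_len(nrow(table)), table$chrom, drop = TRUE)
    for (ch in names(by_chrom)) {
      if (!ch %in% names(lens)) {
        bd_stop("PositionBeyondChromosome",
                sprintf("chromosome '%s' absent from genome metadata", ch))
      }
      L <- lens[[ch]]
      idx <- by_chrom[[ch]]
      pos <- table$pos[idx]
      span <- table$ref_span[idx]
      if (any(pos < 1L) || any(pos + pmax(span - 1L, 0L) > L)) {
        bd_stop("PositionBeyondChromosome",
                sprintf("alignment exceeds length of chromosome '%s'; BAM and genome metadata disagree", ch))
      }
      ## difference array: +1 at start, -1 one past the end
      diffv <- numeric(L + 1L)
      keep <- span > 0L
      starts <- pos[keep]
      ends <- pos[keep] + span[keep]
      add <- tabulate(starts, nbins = L + 1L)
      sub <- tabulate(ends, nbins = L + 1L)
      depth[[ch]] <- as.integer(cumsum(add - sub)[seq_len(L)])
    }
  }

  landscape <- do.call(rbind, lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    bw <- if (is.null(bin_width)) {
      max(1000L, (L %/% 500L) %/% 1000L * 1000L)
    } else {
      as.integer(bin_width)
    }
    starts <- seq.int(1L, L, by = bw)
    ends <- pmin(starts + bw - 1L, L)
    csum <- cumsum(as.numeric(depth[[ch]]))
    tot <- csum[ends] - c(0, csum[starts[-1] - 1L])
    data.frame(chrom = ch, bin_start = starts, bin_end = ends,
               mean_depth = tot / (ends - starts + 1L),
               stringsAsFactors = FALSE)
  }))

  structure(
    list(
      depth = depth,
      landscape = landscape,
      bin_width = bin_width,
      total_depth = sum(vapply(depth, function(d) sum(as.numeric(d)), numeric(1))),
      genome_length = sum(as.numeric(lens))
    ),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("Depth profile over ", length(x$depth), " chromosome(s), ",
      format(x$genome_length, big.mark = ","), " bp; mean depth ",
      signif(x$total_depth / x$genome_length, 4), "\n", sep = "")
  invisible(x)
}

#' Genome fraction exceeding depth thresholds
#'
#' For each threshold, the number and fraction of genomic positions
#' with depth at or above it. Fractions are non-increasing in the
#' threshold by construction.
#'
#' @param profile a `depth_profile`
#' @param thresholds strictly increasing integer thresholds (default
#'   1, 5, 10, 20, 30, 50, 100)
#' @return data.frame with columns threshold, bases, fraction
#' @export
depth_threshold_table <- function(profile,
                                  thresholds = c(1L, 5L, 10L, 20L, 30L, 50L, 100L)) {
  stopifnot(all(diff(thresholds) > 0))
  all_depth <- unlist(profile$depth, use.names = FALSE)
  counts <- vapply(thresholds, function(t) sum(all_depth >= t), numeric(1))
  data.frame(
    threshold = thresholds,
    bases = counts,
    fraction = counts / profile$genome_length
  )
}

## lengths and summed depth of one interval set against a profile
interval_depth_sum <- function(profile, df) {
  tot <- 0
  len <- 0
  for (i in seq_len(nrow(df))) {
    d <- profile$depth[[df$chrom[i]]]
    if (is.null(d)) next
    seg <- d[df$start[i]:df$end[i]]
    tot <- tot + sum(as.numeric(seg))
    len <- len + length(seg)
  }
  c(total = tot, length = len)
}

#' Mean sequencing depth per genomic feature class
#'
#' Mean over all positions of each class (exon, intron, intergenic,
#' ...): the classic on-target diagnostic — an exome capture shows
#' exon depth far above intron and intergenic depth.
#'
#' @param profile a `depth_profile`
#' @param meta a `genome_meta` with at least one feature class
#' @return data.frame with columns feature, length, mean_depth
#' @export
feature_mean_depth <- function(profile, meta) {
  stopifnot(inherits(meta, "genome_meta"), length(meta$features) >= 1L)
  rows <- lapply(names(meta$features), function(nm) {
    s <- interval_depth_sum(profile, meta$features[[nm]])
    data.frame(feature = nm, length = unname(s["length"]),
               mean_depth = if (s["length"] > 0) unname(s["total"] / s["length"]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean depth per chromosome
#' @param profile a `depth_profile`
#' @return data.frame with columns chrom, length, mean_depth
#' @export
chromosome_mean_depth <- function(profile) {
  data.frame(
    chrom = names(profile$depth),
    length = vapply(profile$depth, length, integer(1)),
    mean_depth = vapply(profile$depth, function(d) mean(as.numeric(d)), numeric(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
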