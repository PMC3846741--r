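## Resampling experiment: does a random subsample of reads reproduce
## the global per-read statistics? For each subsample size, `reps`
## independent seeded subsamples are drawn and each statistic
## recomputed; the spread across repetitions shrinks as the size
## grows, and at 1e5 reads scalar statistics are reproduced closely —
## which is why 1e5 is the digest's default subsample size.

CONVERGENCE_STATS <- c("mean_insert_size", "mean_base_quality", "mean_mapq",
                       "n_fraction", "gc_fraction", "mean_read_length")

#' Default read subsample size used by the digest
#'
#' 1e5 reads: the size at which repeated random subsamples reproduce
#' global per-base statistics both precisely and consistently (see
#' [run_convergence()]).
#' @return integer scalar
#' @export
default_sample_size <- function() 100000L

## one streaming pass: per-read scalar contributions for all passing reads
scan_per_read_stats <- function(path, filter = bam_filter(),
                                max_insert = 10000L,
                                yield_size = 200000L) {
  param <- Rsamtools::ScanBamParam(
    flag = filter_to_flag(filter),
    what = c("flag", "mapq", "isize", "seq", "qual")
  )
  bf <- Rsamtools::BamFile(path, yieldSize = as.integer(yield_size))
  open(bf)
  on.exit(close(bf))
  acc <- list()
  repeat {
    res <- Rsamtools::scanBam(bf, param = param)[[1]]
    m <- length(res$flag)
    if (m == 0L) break
    lens <- Biostrings::width(res$seq)
    af <- Biostrings::alphabetFrequency(res$seq, baseOnly = TRUE)
    quals <- as.character(res$qual)
    codes <- utf8ToInt(paste(quals, collapse = "")) - 33L
    qlens <- nchar(quals)
    qual_sum <- as.numeric(rowsum(codes, rep.int(seq_len(m), qlens),
                                  reorder = FALSE))
    proper_first <- bitwAnd(res$flag, 2L) > 0L & bitwAnd(res$flag, 64L) > 0L
    tl <- abs(res$isize)
    insert <- ifelse(proper_first & !is.na(tl) & tl > 0L & tl <= max_insert,
                     tl, NA_integer_)
    acc[[length(acc) + 1L]] <- data.frame(
      read_len = lens,
      qual_sum = qual_sum,
      qual_len = qlens,
      mapq = res$mapq,
      n_count = af[, "other"],
      called = rowSums(af[, BASES, drop = FALSE]),
      gc = rowSums(af[, c("C", "G"), drop = FALSE]),
      insert = insert
    )
  }
  if (!length(acc)) {
    bd_stop("NoReadsPass", sprintf("no alignments in '%s' pass the filter", path))
  }
  do.call(rbind, acc)
}

## statistics over a subset of per-read rows
compute_stats_subset <- function(df, statistics) {
  vapply(statistics, function(s) {
    switch(
      s,
      mean_insert_size = {
        v <- df$insert[!is.na(df$insert)]
        if (length(v)) mean(v) else NA_real_
      },
      mean_base_quality = sum(df$qual_sum) / sum(df$qual_len),
      mean_mapq = mean(df$mapq, na.rm = TRUE),
      n_fraction = sum(as.numeric(df$n_count)) / sum(as.numeric(df$read_len)),
      gc_fraction = sum(as.numeric(df$gc)) / sum(as.numeric(df$called)),
      mean_read_length = mean(df$read_len),
      stop(sprintf("unknown convergence statistic '%s'", s))
    )
  }, numeric(1))
}

#' Resampling convergence of subsample-based statistics
#'
#' Draws `reps` independent seeded subsamples at each size, recomputes
#' each named statistic per subsample, and compares against the global
#' value computed over all passing reads. Repetition `r` at size index
#' `i` uses a seed derived deterministically from the master seed, so
#' the whole experiment is reproducible.
#'
#' @param path BAM file path (validated)
#' @param sizes subsample sizes; `NULL` (default) uses
#'   1e2, 1e3, 1e4, 1e5 truncated to the population size
#' @param reps repetitions per size (default 100)
#' @param statistics statistic names, a subset of: mean_insert_size,
#'   mean_base_quality, mean_mapq, n_fraction, gc_fraction,
#'   mean_read_length
#' @param seed master seed
#' @param filter a [bam_filter()]
#' @return a `convergence_result`: list with `estimates` (data.frame
#'   statistic, size, rep, estimate), `global` (data.frame statistic,
#'   value), `summary` (data.frame statistic, size, min, max, iqr),
#'   `sizes`, `reps`, `seed`, `total_reads`
#' @export
run_convergence <- function(path, sizes = NULL, reps = 100L,
                            statistics = CONVERGENCE_STATS,
                            seed = 17L, filter = bam_filter()) {
  stopifnot(reps >= 2L)
  validate_bam(path)
  df <- scan_per_read_stats(path, filter)
  total <- nrow(df)
  if (is.null(sizes)) {
    sizes <- c(100L, 1000L, 10000L, 100000L)
    sizes <- unique(pmin(sizes, total))
  } else if (any(sizes > total)) {
    bd_stop("SizeExceedsPopulation",
            sprintf("requested size %d exceeds the %d passing reads",
                    max(sizes), total))
  }
  sizes <- sort(as.integer(sizes))
  global <- compute_stats_subset(df, statistics)

  rows <- vector("list", length(sizes) * reps)
  k <- 0L
  for (i in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      idx <- with_seed(bd_child_seed(seed, (i - 1L) * reps + r),
                       sample.int(total, sizes[i]))
      est <- compute_stats_subset(df[idx, , drop = FALSE], statistics)
      k <- k + 1L
      rows[[k]] <- data.frame(statistic = statistics, size = sizes[i],
                              rep = r, estimate = unname(est),
                              stringsAsFactors = FALSE)
    }
  }
  estimates <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(
    estimates, list(estimates$statistic, estimates$size)), function(g) {
      data.frame(statistic = g$statistic[1], size = g$size[1],
                 min = min(g$estimate), max = max(g$estimate),
                 iqr = stats::IQR(g$estimate), stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  structure(
    list(
      estimates = estimates,
      global = data.frame(statistic = statistics, value = unname(global),
                          stringsAsFactors = FALSE),
      summary = summ[order(summ$statistic, summ$size), ],
      sizes = sizes, reps = as.integer(reps), seed = as.integer(seed),
      total_reads = total
    ),
    class = "convergence_result"
  )
}

#' @export
print.convergence_result <- function(x, ...) {
  cat("Convergence experiment: ", x$reps, " reps at sizes ",
      paste(x$sizes, collapse = ", "), " over ", x$total_reads,
      " reads\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write convergence estimates as a tidy CSV
#' @param result a `convergence_result`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_convergence_csv <- function(result, path) {
  utils::write.csv(result$estimates, path, row.names = FALSE)
  invisible(path)
}
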