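## Base composition of sampled reads: uncalled (N) base burden,
## observed vs expected nucleotide frequency, per-read GC, and
## positional mono-/di-/k-mer composition at both read ends.
##
## All positional statistics are computed in sequencing orientation:
## reverse-strand alignments are reverse-complemented back to read
## orientation first, so start-of-read artifacts (primer contamination,
## biased priming) line up across strands.

BASES <- c("A", "C", "G", "T")

## Sequences of a sample in sequencing orientation (DNAStringSet).
sample_read_seqs <- function(sample) {
  rec <- sample$records
  if (is.null(rec$seq) || all(is.na(rec$seq) | rec$seq == "*")) {
    bd_stop("MissingSequence", "no sampled record carries base calls")
  }
  ok <- !is.na(rec$seq) & rec$seq != "*"
  seqs <- Biostrings::DNAStringSet(rec$seq[ok])
  rev_strand <- bitwAnd(rec$flag[ok], 16L) > 0L
  if (any(rev_strand)) {
    seqs[rev_strand] <- Biostrings::reverseComplement(seqs[rev_strand])
  }
  seqs
}

## frequency matrix (positions x symbols) from per-position counts;
## rows normalized over called bases
positional_base_freq <- function(seqs, n_pos) {
  cm <- Biostrings::consensusMatrix(seqs, baseOnly = TRUE)
  n_pos <- min(n_pos, ncol(cm))
  cm <- cm[, seq_len(n_pos), drop = FALSE]
  called <- colSums(cm[BASES, , drop = FALSE])
  freq <- t(cm[BASES, , drop = FALSE]) / called
  data.frame(position = seq_len(n_pos), freq,
             n_count = unname(cm["other", ]),
             check.names = FALSE)
}

top_kmer_table <- function(kmers, top) {
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  tab <- sort(table(kmers), decreasing = TRUE)
  tab <- utils::head(tab, top)
  data.frame(
    kmer = names(tab),
    count = as.integer(tab),
    fraction = as.integer(tab) / length(kmers)
  )
}

#' Base composition profile of a read sample
#'
#' @param sample a `read_sample`
#' @param meta a `genome_meta`; its genome-wide base frequencies give
#'   the expected composition, strand-symmetrized
#'   (E(A) = E(T) = (fA + fT)/2, E(C) = E(G) = (fC + fG)/2) because
#'   reads sample both strands
#' @param k k-mer length for the read-end tables (default 5)
#' @param n_positions how many positions from each read end to profile
#'   (default 10)
#' @param top_kmers how many most-frequent k-mers to report per end
#' @return list with `n_base_fraction`, `fraction_reads_with_n`,
#'   `observed_freq`, `expected_freq`, `obs_exp_ratio`, `gc` (list:
#'   histogram data.frame, mean), `start_base_freq`, `end_base_freq`
#'   (position x base frequency tables; end positions counted from the
#'   read's 3' end), `start_dinuc`, `end_dinuc` (dinucleotide
#'   frequencies at the terminal two positions), `start_kmers`,
#'   `end_kmers`
#' @export
base_composition <- function(sample, meta, k = 5L, n_positions = 10L,
                             top_kmers = 20L) {
  stopifnot(inherits(meta, "genome_meta"), k >= 1L)
  seqs <- sample_read_seqs(sample)
  lens <- Biostrings::width(seqs)

  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  total_bases <- sum(as.numeric(af))
  called_per_read <- rowSums(af[, BASES, drop = FALSE])
  n_per_read <- af[, "other"]
  called_tot <- colSums(af[, BASES, drop = FALSE])

  observed <- called_tot / sum(called_tot)
  f <- unlist(meta$genome_base_freq$freq)[BASES]
  expected <- c(
    A = unname((f["A"] + f["T"]) / 2), C = unname((f["C"] + f["G"]) / 2),
    G = unname((f["C"] + f["G"]) / 2), T = unname((f["A"] + f["T"]) / 2)
  )

  gc_frac <- rowSums(af[, c("C", "G"), drop = FALSE]) / called_per_read
  gc_breaks <- seq(0, 1, by = 0.02)
  gc_ok <- gc_frac[is.finite(gc_frac)]
  gc_counts <- tabulate(findInterval(gc_ok, gc_breaks, rightmost.closed = TRUE),
                        nbins = length(gc_breaks) - 1L)

  rev_seqs <- Biostrings::reverse(seqs)  # end-anchored positions
  start_freq <- positional_base_freq(seqs, n_positions)
  end_freq <- positional_base_freq(rev_seqs, n_positions)

  start2 <- as.character(Biostrings::subseq(seqs[lens >= 2L], 1L, 2L))
  endL <- lens[lens >= 2L]
  end2 <- as.character(Biostrings::subseq(seqs[lens >= 2L],
                                          start = endL - 1L, end = endL))
  keep_k <- lens >= k
  startk <- as.character(Biostrings::subseq(seqs[keep_k], 1L, k))
  kl <- lens[keep_k]
  endk <- as.character(Biostrings::subseq(seqs[keep_k], kl - k + 1L, kl))

  list(
    n_base_fraction = sum(as.numeric(n_per_read)) / total_bases,
    fraction_reads_with_n = mean(n_per_read > 0L),
    observed_freq = as.list(observed),
    expected_freq = as.list(expected),
    obs_exp_ratio = as.list(observed / expected),
    gc = list(
      histogram = data.frame(
        bin_low = utils::head(gc_breaks, -1),
        bin_high = gc_breaks[-1],
        count = gc_counts
      ),
      mean = mean(gc_ok)
    ),
    start_base_freq = start_freq,
    end_base_freq = end_freq,
    start_dinuc = top_kmer_table(start2, 16L),
    end_dinuc = top_kmer_table(end2, 16L),
    start_kmers = top_kmer_table(startk, top_kmers),
    end_kmers = top_kmer_table(endk, top_kmers),
    k = as.integer(k),
    total_bases = total_bases
  )
}

#' Strand balance of mapped reads
#'
#' @param table a `mapping_table`
#' @return named numeric: forward and reverse fractions (sum to 1)
#' @export
strand_fractions <- function(table) {
  if (!nrow(table)) return(c(forward = NA_real_, reverse = NA_real_))
  fwd <- mean(table$strand == "+")
  c(forward = fwd, reverse = 1 - fwd)
}
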