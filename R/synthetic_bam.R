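## Synthetic BAM generator with exact ground truth.
##
## Every statistic the digest reports is controlled by a simulation
## parameter here, and the realized values (not just the requested
## rates) are recorded in a truth record, so tests can compare pipeline
## output against truth either exactly (counts, locations) or within
## Monte-Carlo error (sampled quantities). Reads are emitted error-free
## relative to the reference except explicit N substitution and
## declared indels/soft-clips, so CIGAR classes fully determine the
## mismatch statistics.

#' Simulation specification for a synthetic BAM
#'
#' @param genome a list with `fasta` and `meta` as returned by
#'   [generate_toy_genome()]
#' @param read_count number of alignment records (pairs count as two)
#' @param read_length fixed read length (bp)
#' @param paired emit FR read pairs with TLEN set (leftmost mate
#'   positive)
#' @param insert_mean,insert_sd fragment-length distribution for pairs
#'   (defaults mirror a typical short-insert library: mean 262.6 bp,
#'   sd 60 bp)
#' @param qual_start,qual_decay,qual_sd quality model: mean Phred score
#'   at position p is `qual_start - qual_decay * (p - 1)` plus Gaussian
#'   noise, rounded and clamped to [2, 41]
#' @param n_rate per-base probability of an uncalled (N) base
#' @param strand_forward_fraction probability a single-end read (or a
#'   pair's R1) is forward-strand
#' @param duplicate_rate probability a read (pair) reuses the mapping
#'   location of an earlier one
#' @param softclip_rate,softclip_len per-read probability and length of
#'   a leading soft clip (single-end only)
#' @param insertion_rate,deletion_rate,indel_len per-read probability
#'   and length of a single mid-read insertion/deletion (single-end
#'   only)
#' @param mapq_dist data.frame(mapq, prob) to sample mapping qualities
#'   from; the default gives ~95% of reads the top score 70
#' @param on_target optional list(feature = class name, fraction =
#'   probability a read starts inside that class's intervals)
#' @param unmapped_count extra unmapped records to append (FLAG 0x4)
#' @param seed integer seed; generation is fully deterministic
#' @return a validated list of class `sim_spec`
#' @export
sim_spec <- function(genome,
                     read_count = 1000L,
                     read_length = 100L,
                     paired = FALSE,
                     insert_mean = 262.6,
                     insert_sd = 60,
                     qual_start = 35,
                     qual_decay = 0.05,
                     qual_sd = 2,
                     n_rate = 0.001,
                     strand_forward_fraction = 0.5,
                     duplicate_rate = 0,
                     softclip_rate = 0,
                     softclip_len = 8L,
                     insertion_rate = 0,
                     deletion_rate = 0,
                     indel_len = 2L,
                     mapq_dist = data.frame(mapq = c(70L, 30L, 0L),
                                            prob = c(0.95, 0.04, 0.01)),
                     on_target = NULL,
                     unmapped_count = 0L,
                     seed = 1L) {
  probs <- c(n_rate, strand_forward_fraction, duplicate_rate,
             softclip_rate, insertion_rate, deletion_rate)
  stopifnot(all(probs >= 0 & probs <= 1), read_count >= 0, read_length >= 1)
  if (paired) {
    stopifnot(insert_mean > 0, read_count %% 2 == 0)
    if (softclip_rate > 0 || insertion_rate > 0 || deletion_rate > 0) {
      bd_stop("SpecInfeasible",
              "indel/soft-clip simulation is supported for single-end specs only")
    }
  }
  lens <- unlist(genome$meta$chrom_lengths)
  if (read_length > max(lens)) {
    bd_stop("SpecInfeasible", "read length exceeds every chromosome")
  }
  structure(
    list(genome = genome, read_count = as.integer(read_count),
         read_length = as.integer(read_length), paired = isTRUE(paired),
         insert_mean = insert_mean, insert_sd = insert_sd,
         qual_start = qual_start, qual_decay = qual_decay, qual_sd = qual_sd,
         n_rate = n_rate,
         strand_forward_fraction = strand_forward_fraction,
         duplicate_rate = duplicate_rate,
         softclip_rate = softclip_rate, softclip_len = as.integer(softclip_len),
         insertion_rate = insertion_rate, deletion_rate = deletion_rate,
         indel_len = as.integer(indel_len),
         mapq_dist = mapq_dist, on_target = on_target,
         unmapped_count = as.integer(unmapped_count),
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

## m random base strings of length k (one long draw, split by substring)
rand_base_str <- function(m, k) {
  if (m == 0L) return(character(0))
  big <- paste(sample(BASES, m * k, replace = TRUE), collapse = "")
  substring(big, seq(1L, m * k, by = k), seq(k, m * k, by = k))
}

## quality strings for m reads of length L in sequencing orientation,
## flipped for reverse-strand reads; returns list(qual, col_sums)
make_qual_strings <- function(m, L, spec, rev_strand) {
  scores <- matrix(
    round(spec$qual_start - spec$qual_decay * rep(0:(L - 1L), each = m) +
            stats::rnorm(m * L, 0, spec$qual_sd)),
    nrow = m
  )
  scores[scores < 2] <- 2
  scores[scores > 41] <- 41
  col_sums <- colSums(scores)
  if (any(rev_strand)) {
    scores[rev_strand, ] <- scores[rev_strand, L:1, drop = FALSE]
  }
  flat <- as.integer(t(scores)) + 33L
  big <- intToUtf8(flat)
  starts <- seq(1L, m * L, by = L)
  list(qual = substring(big, starts, starts + L - 1L), col_sums = col_sums)
}

## inject Ns into seqs at rate n_rate; returns list(seq, n_per_read)
inject_n <- function(seqs, n_rate) {
  if (length(seqs) == 0L || n_rate <= 0) {
    return(list(seq = seqs, n_per_read = integer(length(seqs))))
  }
  lens <- nchar(seqs)
  n_per_read <- stats::rbinom(length(seqs), lens, n_rate)
  for (i in which(n_per_read > 0L)) {
    pp <- sample.int(lens[i], n_per_read[i])
    s <- seqs[i]
    for (p in pp) substr(s, p, p) <- "N"
    seqs[i] <- s
  }
  list(seq = seqs, n_per_read = n_per_read)
}

## choose read start positions, optionally biased into a feature class;
## spans too large for the drawn chromosome are clamped to fit
draw_positions <- function(n, span, chrom_lengths, meta, on_target) {
  chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  span <- pmin(span, unname(chrom_lengths[chrom]))
  maxpos <- unname(chrom_lengths[chrom]) - span + 1L
  pos <- 1L + as.integer(floor(stats::runif(n) * maxpos))
  if (!is.null(on_target)) {
    iv <- meta$features[[on_target$feature]]
    stopifnot(!is.null(iv), nrow(iv) > 0)
    hit <- stats::runif(n) < on_target$fraction
    if (any(hit)) {
      m <- sum(hit)
      widths <- iv$end - iv$start + 1L
      pick <- sample.int(nrow(iv), m, replace = TRUE, prob = widths)
      p <- iv$start[pick] +
        as.integer(floor(stats::runif(m) * widths[pick]))
      ch <- iv$chrom[pick]
      p <- pmin(p, chrom_lengths[ch] - span[hit] + 1L)
      chrom[hit] <- ch
      pos[hit] <- pmax(1L, p)
      span[hit] <- pmin(span[hit], unname(chrom_lengths[ch]))
    }
  }
  list(chrom = chrom, pos = as.integer(pos), span = as.integer(span))
}

## extract reference segments [pos, pos + span - 1] per read
extract_ref <- function(dna, chrom, pos, span) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    v <- Biostrings::Views(dna[[ch]], start = pos[i], end = pos[i] + span[i] - 1L)
    out[i] <- as.character(v)
  }
  out
}

#' Generate a sorted, indexed synthetic BAM with ground truth
#'
#' @param spec a [sim_spec()]
#' @param out_path output BAM path (".bam" appended if missing)
#' @param write_truth_json also write the truth record (summaries, and
#'   per-read locations when `read_count` <= 20000) as JSON next to
#'   the BAM
#' @return list with `bam` (path), `truth` (list of realized
#'   quantities), `truth_json` (path or NULL)
#' @export
generate_synthetic_bam <- function(spec, out_path, write_truth_json = TRUE) {
  stopifnot(inherits(spec, "sim_spec"))
  out_path <- sub("\\.bam$", "", out_path)
  meta <- spec$genome$meta
  chrom_lengths <- unlist(meta$chrom_lengths)
  dna <- Biostrings::readDNAStringSet(spec$genome$fasta)
  names(dna) <- sub("\\s.*$", "", names(dna))
  L <- spec$read_length
  n <- spec$read_count

  rec <- with_seed(spec$seed, {
    if (n == 0L) {
      data.frame(qname = character(0), flag = integer(0), chrom = character(0),
                 pos = integer(0), mapq = integer(0), cigar = character(0),
                 rnext = character(0), pnext = integer(0), tlen = integer(0),
                 seq = character(0), qual = character(0),
                 frag = integer(0), stringsAsFactors = FALSE)
    } else if (spec$paired) {
      simulate_paired(spec, dna, chrom_lengths, meta)
    } else {
      simulate_single(spec, dna, chrom_lengths, meta)
    }
  })
  n_requested_dup <- attr(rec, "n_requested_dup")
  if (is.null(n_requested_dup)) n_requested_dup <- 0L

  ## N substitution and qualities (chunked to bound memory)
  n_per_read <- integer(nrow(rec))
  qual_pos_sums <- numeric(L)
  if (nrow(rec)) {
    rec <- with_seed(bd_child_seed(spec$seed, 1L), {
      inj <- inject_n(rec$seq, spec$n_rate)
      rec$seq <- inj$seq
      n_per_read <- inj$n_per_read
      rev_strand <- bitwAnd(rec$flag, 16L) > 0L
      chunk <- 100000L
      quals <- character(nrow(rec))
      for (s in seq(1L, nrow(rec), by = chunk)) {
        e <- min(s + chunk - 1L, nrow(rec))
        q <- make_qual_strings(e - s + 1L, L, spec, rev_strand[s:e])
        quals[s:e] <- q$qual
        qual_pos_sums <- qual_pos_sums + q$col_sums
      }
      rec$qual <- quals
      rec
    })
  }

  ## unmapped tail records
  if (spec$unmapped_count > 0L) {
    un <- with_seed(bd_child_seed(spec$seed, 2L), data.frame(
      qname = sprintf("unm%d", seq_len(spec$unmapped_count)),
      flag = 4L, chrom = "*", pos = 0L, mapq = 0L, cigar = "*",
      rnext = "*", pnext = 0L, tlen = 0L,
      seq = rand_base_str(spec$unmapped_count, L),
      qual = strrep("I", L), frag = NA_integer_,
      stringsAsFactors = FALSE
    ))
    rec <- rbind(rec, un)
  }

  ## coordinate sort (mapped records by reference order then position;
  ## unmapped at the end)
  chrom_idx <- match(rec$chrom, names(chrom_lengths))
  chrom_idx[is.na(chrom_idx)] <- length(chrom_lengths) + 1L
  ord <- order(chrom_idx, rec$pos)
  rec <- rec[ord, , drop = FALSE]

  sam <- paste0(out_path, ".sam")
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            unname(chrom_lengths))
  )
  body <- if (nrow(rec)) {
    paste(rec$qname, rec$flag, rec$chrom, rec$pos, rec$mapq, rec$cigar,
          rec$rnext, rec$pnext, rec$tlen, rec$seq, rec$qual, sep = "\t")
  } else {
    character(0)
  }
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, out_path, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)

  mrec <- rec[bitwAnd(rec$flag, 4L) == 0L, , drop = FALSE]
  key <- paste(mrec$chrom, mrec$pos,
               ifelse(bitwAnd(mrec$flag, 16L) > 0L, "-", "+"), sep = "\r")
  mult <- table(table(key))
  af <- if (nrow(rec)) {
    Biostrings::alphabetFrequency(Biostrings::DNAStringSet(rec$seq),
                                  baseOnly = TRUE)
  } else {
    matrix(0, 0, 5, dimnames = list(NULL, c(BASES, "other")))
  }
  called <- sum(af[, BASES])
  first_in_pair <- bitwAnd(mrec$flag, 64L) > 0L
  frag <- mrec$frag[first_in_pair & !is.na(mrec$frag) & mrec$frag > 0L]

  truth <- list(
    spec_seed = spec$seed,
    read_count = n,
    unmapped_count = spec$unmapped_count,
    n_requested_dup = n_requested_dup,
    locations = data.frame(
      chrom = mrec$chrom, pos = mrec$pos,
      strand = ifelse(bitwAnd(mrec$flag, 16L) > 0L, "-", "+"),
      mapq = mrec$mapq,
      ref_span = if (nrow(mrec)) cigar_ref_span(mrec$cigar) else integer(0),
      stringsAsFactors = FALSE
    ),
    flags = rec$flag,
    cigars = mrec$cigar,
    multiplicity_histogram = data.frame(
      multiplicity = as.integer(names(mult)),
      locations = as.integer(mult)
    ),
    n_bases = sum(n_per_read),
    reads_with_n = sum(n_per_read > 0L),
    total_bases = as.numeric(nrow(rec)) * L,
    gc_fraction = if (called > 0) sum(af[, c("C", "G")]) / called else NA_real_,
    forward_fraction = if (nrow(mrec)) {
      mean(bitwAnd(mrec$flag, 16L) == 0L)
    } else {
      NA_real_
    },
    mapq_table = as.data.frame(table(mapq = mrec$mapq),
                               stringsAsFactors = FALSE),
    insert_sizes_mean = if (length(frag)) mean(frag) else NA_real_,
    insert_sizes_sd = if (length(frag)) stats::sd(frag) else NA_real_,
    n_fragments = length(frag),
    qual_position_mean = if (nrow(rec)) qual_pos_sums / nrow(rec) else numeric(0)
  )

  truth_json <- NULL
  if (write_truth_json) {
    truth_json <- paste0(out_path, ".truth.json")
    slim <- truth
    if (n > 20000L) {
      slim$locations <- NULL
      slim$flags <- NULL
      slim$cigars <- NULL
    }
    writeLines(jsonlite::toJSON(slim, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"), truth_json)
  }
  list(bam = bam, truth = truth, truth_json = truth_json)
}

## single-end record simulation (inside the master-seed RNG scope)
simulate_single <- function(spec, dna, chrom_lengths, meta) {
  n <- spec$read_count
  L <- spec$read_length
  is_dup <- stats::runif(n) < spec$duplicate_rate
  is_dup[1L] <- FALSE
  orig <- which(!is_dup)
  n_orig <- length(orig)

  p_sc <- spec$softclip_rate
  p_in <- spec$insertion_rate
  p_de <- spec$deletion_rate
  type_o <- sample(c("plain", "softclip", "ins", "del"), n_orig, replace = TRUE,
                   prob = c(max(0, 1 - p_sc - p_in - p_de), p_sc, p_in, p_de))
  span_of <- function(ty) {
    ifelse(ty == "plain", L,
           ifelse(ty == "softclip", L - spec$softclip_len,
                  ifelse(ty == "ins", L - spec$indel_len, L + spec$indel_len)))
  }
  span_o <- as.integer(span_of(type_o))
  loc <- draw_positions(n_orig, span_o, chrom_lengths, meta, spec$on_target)
  strand_fwd_o <- stats::runif(n_orig) < spec$strand_forward_fraction

  ## expand to all reads: duplicates copy an origin's location wholesale
  type <- character(n); chrom <- character(n); pos <- integer(n)
  span <- integer(n); fwd <- logical(n)
  type[orig] <- type_o; chrom[orig] <- loc$chrom; pos[orig] <- loc$pos
  span[orig] <- span_o; fwd[orig] <- strand_fwd_o
  if (any(is_dup)) {
    parent <- orig[sample.int(n_orig, sum(is_dup), replace = TRUE)]
    type[is_dup] <- type[parent]; chrom[is_dup] <- chrom[parent]
    pos[is_dup] <- pos[parent]; span[is_dup] <- span[parent]
    fwd[is_dup] <- fwd[parent]
  }

  a_del <- L %/% 2L
  a_ins <- L %/% 2L
  cigar <- character(n)
  cigar[type == "plain"] <- sprintf("%dM", L)
  cigar[type == "softclip"] <- sprintf("%dS%dM", spec$softclip_len,
                                       L - spec$softclip_len)
  cigar[type == "ins"] <- sprintf("%dM%dI%dM", a_ins, spec$indel_len,
                                  L - a_ins - spec$indel_len)
  cigar[type == "del"] <- sprintf("%dM%dD%dM", a_del, spec$indel_len,
                                  L - a_del)

  ref <- extract_ref(dna, chrom, pos, span)
  seq <- ref
  i <- type == "softclip"
  if (any(i)) seq[i] <- paste0(rand_base_str(sum(i), spec$softclip_len), ref[i])
  i <- type == "ins"
  if (any(i)) {
    seq[i] <- paste0(substr(ref[i], 1L, a_ins),
                     rand_base_str(sum(i), spec$indel_len),
                     substr(ref[i], a_ins + 1L, span[i]))
  }
  i <- type == "del"
  if (any(i)) {
    seq[i] <- paste0(substr(ref[i], 1L, a_del),
                     substr(ref[i], a_del + spec$indel_len + 1L, span[i]))
  }

  mapq <- sample(spec$mapq_dist$mapq, n, replace = TRUE,
                 prob = spec$mapq_dist$prob)
  out <- data.frame(
    qname = sprintf("sim%d", seq_len(n)),
    flag = ifelse(fwd, 0L, 16L),
    chrom = chrom, pos = pos, mapq = as.integer(mapq), cigar = cigar,
    rnext = "*", pnext = 0L, tlen = 0L, seq = seq, qual = "",
    frag = NA_integer_, stringsAsFactors = FALSE
  )
  attr(out, "n_requested_dup") <- sum(is_dup)
  out
}

## paired-end record simulation (FR orientation, leftmost TLEN positive)
simulate_paired <- function(spec, dna, chrom_lengths, meta) {
  n_pairs <- spec$read_count %/% 2L
  L <- spec$read_length
  is_dup <- stats::runif(n_pairs) < spec$duplicate_rate
  is_dup[1L] <- FALSE
  orig <- which(!is_dup)
  frag_o <- pmax(as.integer(round(stats::rnorm(length(orig), spec$insert_mean,
                                               spec$insert_sd))), L)
  frag_o <- pmin(frag_o, max(chrom_lengths))
  loc <- draw_positions(length(orig), frag_o, chrom_lengths, meta,
                        spec$on_target)
  frag_o <- loc$span  # clamped to the drawn chromosome
  r1_fwd_o <- stats::runif(length(orig)) < spec$strand_forward_fraction

  frag <- integer(n_pairs); chrom <- character(n_pairs)
  left <- integer(n_pairs); r1_fwd <- logical(n_pairs)
  frag[orig] <- frag_o; chrom[orig] <- loc$chrom
  left[orig] <- loc$pos; r1_fwd[orig] <- r1_fwd_o
  if (any(is_dup)) {
    parent <- orig[sample.int(length(orig), sum(is_dup), replace = TRUE)]
    frag[is_dup] <- frag[parent]; chrom[is_dup] <- chrom[parent]
    left[is_dup] <- left[parent]; r1_fwd[is_dup] <- r1_fwd[parent]
  }
  right <- left + frag - L

  mapq <- matrix(sample(spec$mapq_dist$mapq, 2L * n_pairs, replace = TRUE,
                        prob = spec$mapq_dist$prob), ncol = 2L)
  seq_l <- extract_ref(dna, chrom, left, rep(L, n_pairs))
  seq_r <- extract_ref(dna, chrom, right, rep(L, n_pairs))

  qn <- sprintf("pair%d", seq_len(n_pairs))
  ## left mate is forward, right mate reverse (FR); R1 is left iff r1_fwd
  left_rec <- data.frame(
    qname = qn,
    flag = ifelse(r1_fwd, 99L, 163L),
    chrom = chrom, pos = left,
    mapq = mapq[, 1L],
    cigar = sprintf("%dM", L), rnext = "=", pnext = right,
    tlen = frag, seq = seq_l, qual = "", frag = frag,
    stringsAsFactors = FALSE
  )
  right_rec <- data.frame(
    qname = qn,
    flag = ifelse(r1_fwd, 147L, 83L),
    chrom = chrom, pos = right,
    mapq = mapq[, 2L],
    cigar = sprintf("%dM", L), rnext = "=", pnext = left,
    tlen = -frag, seq = seq_r, qual = "", frag = frag,
    stringsAsFactors = FALSE
  )
  out <- rbind(left_rec, right_rec)
  attr(out, "n_requested_dup") <- sum(is_dup)
  out
}
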