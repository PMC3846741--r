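# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture_dir <- function() {
  if (is.null(.fixture_cache$dir)) {
    .fixture_cache$dir <- file.path(tempdir(), "bamdigest-fixtures")
    dir.create(.fixture_cache$dir, showWarnings = FALSE, recursive = TRUE)
  }
  .fixture_cache$dir
}

## toy genome: 2 chromosomes, 100 kb total, uniform composition, 8 genes
toy_genome <- function() {
  if (is.null(.fixture_cache$genome)) {
    .fixture_cache$genome <- generate_toy_genome(
      file.path(fixture_dir(), "toy"), seed = 101L)
  }
  .fixture_cache$genome
}

## standard small single-end simulation (2,000 reads, mixed CIGARs, dups)
toy_single_sim <- function() {
  if (is.null(.fixture_cache$single)) {
    spec <- sim_spec(toy_genome(), read_count = 2000L, duplicate_rate = 0.1,
                     softclip_rate = 0.05, deletion_rate = 0.03,
                     insertion_rate = 0.02, n_rate = 0.002, seed = 202L)
    .fixture_cache$single <- generate_synthetic_bam(
      spec, file.path(fixture_dir(), "single.bam"), write_truth_json = FALSE)
    .fixture_cache$single$spec <- spec
  }
  .fixture_cache$single
}

## standard small paired simulation (4,000 records = 2,000 pairs)
toy_paired_sim <- function() {
  if (is.null(.fixture_cache$paired)) {
    spec <- sim_spec(toy_genome(), read_count = 4000L, paired = TRUE,
                     n_rate = 0.001, seed = 303L)
    .fixture_cache$paired <- generate_synthetic_bam(
      spec, file.path(fixture_dir(), "paired.bam"), write_truth_json = FALSE)
    .fixture_cache$paired$spec <- spec
  }
  .fixture_cache$paired
}

## hand-rolled BAM from explicit SAM records, for surgical flag/CIGAR cases
write_test_bam <- function(records, refs = c(chr1 = 10000L),
                           sort_order = "coordinate",
                           index = TRUE,
                           name = paste0("hand", as.integer(stats::runif(1, 1, 1e8)))) {
  dir <- fixture_dir()
  sam <- file.path(dir, paste0(name, ".sam"))
  header <- c(
    sprintf("@HD\tVN:1.6\tSO:%s", sort_order),
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), unname(refs))
  )
  body <- if (NROW(records)) {
    do.call(paste, c(unname(as.list(records)), sep = "\t"))
  } else {
    character(0)
  }
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE,
                          indexDestination = index)
  unlink(sam)
  bam
}

## SAM record constructor with sane defaults
sam_record <- function(qname = "r1", flag = 0L, chrom = "chr1", pos = 100L,
                       mapq = 60L, cigar = "10M", rnext = "*", pnext = 0L,
                       tlen = 0L, seq = strrep("A", 10L),
                       qual = strrep("I", nchar(seq))) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

## minimal in-memory read_sample (no BAM behind it)
fake_sample <- function(records) {
  structure(list(records = records, requested_n = nrow(records),
                 total_seen = nrow(records), seed = 0L),
            class = "read_sample")
}

## write a small FASTA from named character sequences
write_test_fasta <- function(seqs, name = "mini") {
  path <- file.path(fixture_dir(), paste0(name, ".fa"))
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}
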