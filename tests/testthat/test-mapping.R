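# brute-force FLAG oracle: re-derive category counts bit by bit
naive_flag_counts <- function(flags) {
  bits <- c(paired = 1L, properly_paired = 2L, unmapped = 4L,
            mate_unmapped = 8L, reverse_strand = 16L,
            mate_reverse_strand = 32L, first_in_pair = 64L,
            second_in_pair = 128L, secondary = 256L, duplicate = 1024L,
            supplementary = 2048L)
  out <- numeric(length(bits))
  names(out) <- names(bits)
  for (f in flags) {
    for (b in names(bits)) {
      if (bitwAnd(f, bits[[b]]) > 0L) out[b] <- out[b] + 1
    }
  }
  c(total = length(flags), mapped = sum(bitwAnd(flags, 4L) == 0L), out)
}

test_that("FLAG categories decode the documented examples", {
  fs <- flag_summary(c(99L, 147L, 83L, 163L))
  expect_equal(unname(fs["paired"]), 4)
  expect_equal(unname(fs["properly_paired"]), 4)
  expect_equal(unname(fs["unmapped"]), 0)
  expect_equal(unname(fs["reverse_strand"]), 2)

  expect_equal(unname(flag_summary(4L)["unmapped"]), 1)
})

test_that("FLAG tabulation equals the per-bit oracle on random mixtures", {
  set.seed(7)
  flags <- as.integer(sample(0:4095, 500, replace = TRUE))
  expect_equal(flag_summary(flags), naive_flag_counts(flags))
})

test_that("mapq thresholds count reads at or above each cutoff", {
  tab <- data.frame(mapq = rep(70L, 5))
  ms <- mapq_summary(tab, cutoffs = 70L)
  expect_equal(ms$thresholds$fraction, 1)

  tab2 <- data.frame(mapq = c(0L, 30L, 70L))
  ms2 <- mapq_summary(tab2, cutoffs = c(30L, 70L))
  expect_equal(ms2$thresholds$fraction, c(2 / 3, 1 / 3))
  expect_equal(ms2$histogram$count, c(1L, 1L, 1L))
})

test_that("mapq histogram matches generator truth exactly", {
  sim <- toy_single_sim()
  tab <- scan_mapping_locations(sim$bam)
  ms <- mapq_summary(tab)
  truth <- sim$truth$mapq_table
  expect_equal(ms$histogram$mapq, as.integer(truth$mapq))
  expect_equal(ms$histogram$count, truth$Freq)
})

test_that("mismatch fractions follow the CIGAR classes", {
  mk <- function(cigars) fake_sample(data.frame(
    qname = paste0("r", seq_along(cigars)), flag = 0L, chrom = "chr1",
    pos = 1L, mapq = 60L, cigar = cigars, tlen = 0L,
    seq = strrep("A", 75), stringsAsFactors = FALSE))

  all_m <- mismatch_summary(mk(rep("75M", 10)))
  expect_equal(unname(all_m$base_fractions["M"]), 1)
  expect_equal(all_m$reads_with_indel_or_clip, 0)

  dels <- mismatch_summary(mk(rep("20M1D55M", 4)))
  expect_equal(all_m$base_fractions[["M"]], 1)
  expect_equal(dels$reads_with_indel_or_clip, 1)
  # deleted bases normalized by reference span: 4 D over 4 x 76
  expect_equal(unname(dels$base_fractions["D"]), 4 / (4 * 76))

  mixed <- mismatch_summary(mk(c("10S65M", rep("75M", 9))))
  expect_equal(unname(mixed$base_fractions["S"]), 10 / 750)
  expect_equal(mixed$reads_with_indel_or_clip, 0.1)
})

test_that("duplication histogram counts locations by multiplicity", {
  tab <- data.frame(
    chrom = "chr1", pos = c(100L, 100L, 100L, 200L),
    strand = "+", stringsAsFactors = FALSE)
  h <- duplication_histogram(tab)
  expect_equal(h$multiplicity, c(1L, 3L))
  expect_equal(h$locations, c(1L, 1L))
  expect_equal(sum(h$multiplicity * h$locations), nrow(tab))

  distinct <- data.frame(chrom = "chr1", pos = 1:7 * 10L, strand = "+",
                         stringsAsFactors = FALSE)
  h2 <- duplication_histogram(distinct)
  expect_equal(h2$multiplicity, 1L)
  expect_equal(h2$locations, 7L)

  # same position on opposite strands is two locations
  two_strand <- data.frame(chrom = "chr1", pos = 100L,
                           strand = c("+", "-"), stringsAsFactors = FALSE)
  expect_equal(duplication_histogram(two_strand)$locations, 2L)
})

test_that("duplication histogram matches generator truth exactly", {
  sim <- toy_single_sim()
  tab <- scan_mapping_locations(sim$bam)
  h <- duplication_histogram(tab)
  truth <- sim$truth$multiplicity_histogram
  expect_equal(h$multiplicity, truth$multiplicity)
  expect_equal(h$locations, truth$locations)
})

test_that("insert sizes use first-in-pair |TLEN| and mark single-end absent", {
  paired <- fake_sample(data.frame(
    qname = c("p1", "p1", "p2", "p2"),
    flag = c(99L, 147L, 99L, 147L), chrom = "chr1",
    pos = c(1L, 151L, 1L, 251L), mapq = 60L, cigar = "50M",
    tlen = c(200L, -200L, 300L, -300L), seq = strrep("A", 50),
    stringsAsFactors = FALSE))
  iss <- insert_size_summary(paired)
  expect_false(iss$absent)
  expect_equal(iss$mean, 250)
  expect_equal(iss$n_pairs, 2L)

  single <- fake_sample(data.frame(
    qname = "s", flag = 0L, chrom = "chr1", pos = 1L, mapq = 60L,
    cigar = "50M", tlen = 0L, seq = strrep("A", 50),
    stringsAsFactors = FALSE))
  expect_true(insert_size_summary(single)$absent)
})

test_that("the insert-size cap excludes artifacts but reports them", {
  s <- fake_sample(data.frame(
    qname = c("a", "b"), flag = 99L, chrom = "chr1", pos = 1L, mapq = 60L,
    cigar = "50M", tlen = c(300L, 50000L), seq = strrep("A", 50),
    stringsAsFactors = FALSE))
  iss <- insert_size_summary(s, max_abs = 10000L)
  expect_equal(iss$n_pairs, 1L)
  expect_equal(iss$n_excluded, 1L)
  expect_equal(iss$mean, 300)
})

test_that("strand fractions sum to one", {
  tab <- data.frame(strand = c("+", "+", "-", "+"))
  sf <- strand_fractions(tab)
  expect_equal(unname(sf["forward"]), 0.75)
  expect_equal(sum(sf), 1)
})
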