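test_that("validate_bam accepts a sorted, indexed BAM and reports the header", {
  sim <- toy_single_sim()
  info <- validate_bam(sim$bam)
  expect_s3_class(info, "bam_header_info")
  expect_identical(info$sort_order, "coordinate")
  expect_true(info$has_index)
  expect_setequal(info$references$name, c("chr1", "chr2"))
  expect_true(all(info$references$length > 0))
})

test_that("validate_bam rejects missing, unsorted, and unindexed inputs", {
  expect_error(validate_bam(file.path(fixture_dir(), "nope.bam")),
               class = "bamdigest_MissingFile")

  unsorted <- write_test_bam(sam_record(), sort_order = "unsorted",
                             index = FALSE, name = "unsorted")
  expect_error(validate_bam(unsorted), class = "bamdigest_NotCoordinateSorted")

  noindex <- write_test_bam(sam_record(), index = FALSE, name = "noindex")
  expect_error(validate_bam(noindex), class = "bamdigest_MissingIndex")
})

test_that("scan_mapping_locations reproduces generator truth", {
  sim <- toy_single_sim()
  tab <- scan_mapping_locations(sim$bam)
  truth <- sim$truth$locations
  key <- function(d) order(d$chrom, d$pos, d$strand, d$mapq, d$ref_span)
  tr <- truth[key(truth), ]
  sc <- tab[key(tab), ]
  expect_equal(as.character(sc$chrom), tr$chrom)
  expect_equal(sc$pos, tr$pos)
  expect_equal(sc$strand, tr$strand)
  expect_equal(sc$mapq, tr$mapq)
  expect_equal(sc$ref_span, tr$ref_span)
  expect_true(!is.unsorted(order(as.integer(sc$chrom), sc$pos)))
})

test_that("empty and filtered inputs are counted conservatively", {
  g <- toy_genome()
  empty <- generate_synthetic_bam(
    sim_spec(g, read_count = 0L, seed = 1L),
    file.path(fixture_dir(), "empty.bam"), write_truth_json = FALSE)
  tab <- scan_mapping_locations(empty$bam)
  expect_identical(nrow(tab), 0L)

  # unmapped reads are excluded from the table but present in the total
  mixed <- generate_synthetic_bam(
    sim_spec(g, read_count = 300L, unmapped_count = 25L, seed = 2L),
    file.path(fixture_dir(), "mixed.bam"), write_truth_json = FALSE)
  tab <- scan_mapping_locations(mixed$bam)
  expect_identical(nrow(tab), 300L)
  expect_identical(attr(tab, "total_alignments"), 325L)
  expect_identical(attr(tab, "filtered_out"), 25L)
})

test_that("secondary alignments are excluded by the default filter", {
  recs <- rbind(
    sam_record(qname = "r1", flag = 0L, pos = 100L),
    sam_record(qname = "r1", flag = 256L, pos = 300L, seq = "*", qual = "*")
  )
  bam <- write_test_bam(recs, name = "secondary")
  tab <- scan_mapping_locations(bam)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$pos, 100L)
  # ... but the FLAG tabulation still sees both records
  fs <- flag_summary(bam)
  expect_identical(unname(fs["total"]), 2)
  expect_identical(unname(fs["secondary"]), 1)
})

test_that("sample_full_records returns everything when n exceeds the population", {
  sim <- toy_single_sim()
  s <- sample_full_records(sim$bam, n = 10000L, seed = 1L)
  expect_identical(nrow(s$records), 2000L)
  expect_identical(s$total_seen, 2000L)
})

test_that("sampling is deterministic for a fixed seed and errors on empty input", {
  sim <- toy_single_sim()
  s1 <- sample_full_records(sim$bam, n = 200L, seed = 7L)
  s2 <- sample_full_records(sim$bam, n = 200L, seed = 7L)
  expect_identical(s1$records, s2$records)
  s3 <- sample_full_records(sim$bam, n = 200L, seed = 8L)
  expect_false(identical(s1$records, s3$records))

  g <- toy_genome()
  empty <- generate_synthetic_bam(
    sim_spec(g, read_count = 0L, seed = 1L),
    file.path(fixture_dir(), "empty2.bam"), write_truth_json = FALSE)
  expect_error(sample_full_records(empty$bam, n = 10L, seed = 1L),
               class = "bamdigest_NoReadsPass")
})

test_that("reservoir sampling is uniform over reads", {
  # 200 repetitions of n = 50 from a 1,000-read BAM; per-read inclusion
  # should be Binomial(200, 0.05): chi-square goodness of fit on the
  # total inclusion counts per read
  g <- toy_genome()
  sim <- generate_synthetic_bam(
    sim_spec(g, read_count = 1000L, seed = 55L),
    file.path(fixture_dir(), "unif.bam"), write_truth_json = FALSE)
  counts <- integer(1000L)
  for (r in 1:200) {
    s <- sample_full_records(sim$bam, n = 50L, seed = r,
                             yield_size = 300L)  # force multi-chunk streaming
    expect_identical(nrow(s$records), 50L)
    idx <- as.integer(sub("^sim", "", s$records$qname))
    counts[idx] <- counts[idx] + 1L
  }
  expect_identical(sum(counts), 200L * 50L)
  expected <- rep(200 * 50 / 1000, 1000)
  chisq <- sum((counts - expected)^2 / expected)
  p <- stats::pchisq(chisq, df = 999, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("sampled ref_span agrees with cigar_stats across modules", {
  sim <- toy_single_sim()
  s <- sample_full_records(sim$bam, n = 300L, seed = 3L)
  spans <- vapply(s$records$cigar, function(cg) cigar_stats(cg)$ref_span,
                  integer(1))
  tab <- scan_mapping_locations(sim$bam)
  key_tab <- paste(tab$chrom, tab$pos, tab$ref_span)
  key_s <- paste(s$records$chrom, s$records$pos, spans)
  expect_true(all(key_s %in% key_tab))
})
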