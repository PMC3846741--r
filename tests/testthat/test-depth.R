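# naive pileup oracle: increment every covered base, read by read
naive_depth <- function(table, chrom_lengths) {
  depth <- lapply(chrom_lengths, function(L) integer(L))
  for (i in seq_len(nrow(table))) {
    ch <- as.character(table$chrom[i])
    span <- table$ref_span[i]
    if (span > 0) {
      idx <- table$pos[i]:(table$pos[i] + span - 1L)
      depth[[ch]][idx] <- depth[[ch]][idx] + 1L
    }
  }
  depth
}

fake_profile <- function(depths) {
  structure(list(
    depth = depths,
    genome_length = sum(vapply(depths, length, integer(1))),
    total_depth = sum(vapply(depths, function(d) sum(as.numeric(d)), numeric(1)))
  ), class = "depth_profile")
}

test_that("a single read produces a unit-depth interval", {
  g <- toy_genome()
  tab <- structure(
    data.frame(chrom = factor("chr1", levels = c("chr1", "chr2")),
               pos = 100L, strand = "+", mapq = 60L, ref_span = 75L),
    class = c("mapping_table", "data.frame"))
  prof <- compute_depth(tab, g$meta)
  d <- prof$depth$chr1
  expect_true(all(d[100:174] == 1L))
  expect_identical(sum(d), 75L)
  expect_true(all(prof$depth$chr2 == 0L))
})

test_that("pileup equals the naive oracle on random synthetic data", {
  g <- toy_genome()
  sim <- toy_single_sim()
  tab <- scan_mapping_locations(sim$bam)
  prof <- compute_depth(tab, g$meta)
  oracle <- naive_depth(tab, unlist(g$meta$chrom_lengths))
  expect_identical(prof$depth$chr1, oracle$chr1)
  expect_identical(prof$depth$chr2, oracle$chr2)
})

test_that("pileup conserves aligned reference bases and handles empty input", {
  g <- toy_genome()
  sim <- toy_single_sim()
  tab <- scan_mapping_locations(sim$bam)
  prof <- compute_depth(tab, g$meta)
  expect_identical(prof$total_depth, sum(as.numeric(tab$ref_span)))

  empty <- tab[0, , drop = FALSE]
  prof0 <- compute_depth(empty, g$meta)
  expect_identical(prof0$total_depth, 0)
  expect_true(all(unlist(prof0$depth) == 0L))
})

test_that("reads beyond the chromosome signal metadata mismatch", {
  g <- toy_genome()
  tab <- data.frame(chrom = factor("chr2", levels = c("chr1", "chr2")),
                    pos = 39990L, strand = "+", mapq = 60L, ref_span = 75L)
  expect_error(compute_depth(tab, g$meta),
               class = "bamdigest_PositionBeyondChromosome")
})

test_that("threshold table counts known depths and stays monotone", {
  prof <- fake_profile(list(c1 = c(0L, 1L, 1L, 3L)))
  tt <- depth_threshold_table(prof, c(1L, 2L, 3L))
  expect_equal(tt$bases, c(3, 1, 1))
  expect_equal(tt$fraction, c(0.75, 0.25, 0.25))

  expect_equal(depth_threshold_table(prof, 0L)$fraction, 1.0)

  zero <- fake_profile(list(c1 = integer(10)))
  expect_equal(depth_threshold_table(zero, c(1L, 5L, 10L))$bases, c(0, 0, 0))

  sim <- toy_single_sim()
  tab <- scan_mapping_locations(sim$bam)
  prof2 <- compute_depth(tab, toy_genome()$meta)
  fr <- depth_threshold_table(prof2)$fraction
  expect_true(all(diff(fr) <= 0))
})

test_that("feature mean depth isolates covered classes", {
  depths <- list(c1 = c(rep(0L, 10), rep(10L, 20), rep(0L, 70)))
  prof <- fake_profile(depths)
  meta <- structure(list(
    chrom_lengths = list(c1 = 100L),
    features = list(exon = data.frame(chrom = "c1", start = 11L, end = 30L),
                    intergenic = data.frame(chrom = "c1",
                                            start = c(1L, 31L),
                                            end = c(10L, 100L)))
  ), class = "genome_meta")
  fm <- feature_mean_depth(prof, meta)
  expect_equal(fm$mean_depth[fm$feature == "exon"], 10)
  expect_equal(fm$mean_depth[fm$feature == "intergenic"], 0)

  whole <- structure(list(
    chrom_lengths = list(c1 = 100L),
    features = list(all = data.frame(chrom = "c1", start = 1L, end = 100L))
  ), class = "genome_meta")
  fm2 <- feature_mean_depth(prof, whole)
  expect_equal(fm2$mean_depth, prof$total_depth / prof$genome_length)
})

test_that("an exome-like simulation shows exon > intron > background depth", {
  g <- toy_genome()
  spec <- sim_spec(g, read_count = 8000L, on_target = list(feature = "exon",
                                                           fraction = 0.85),
                   seed = 404L)
  sim <- generate_synthetic_bam(spec, file.path(fixture_dir(), "exome.bam"),
                                write_truth_json = FALSE)
  tab <- scan_mapping_locations(sim$bam)
  prof <- compute_depth(tab, g$meta)
  fm <- feature_mean_depth(prof, g$meta)
  means <- stats::setNames(fm$mean_depth, fm$feature)
  expect_gt(means["exon"], means["intron"])
  expect_gt(means["intron"], 0)
  expect_gt(means["exon"], 5 * means["intergenic"])
})

test_that("landscape bins average the per-base depth", {
  g <- toy_genome()
  sim <- toy_single_sim()
  tab <- scan_mapping_locations(sim$bam)
  prof <- compute_depth(tab, g$meta, bin_width = 5000L)
  first <- prof$landscape[prof$landscape$chrom == "chr1", ][1, ]
  expect_equal(first$mean_depth,
               mean(prof$depth$chr1[first$bin_start:first$bin_end]))
  covered <- sum((prof$landscape$bin_end - prof$landscape$bin_start + 1))
  expect_equal(covered, prof$genome_length)
})
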