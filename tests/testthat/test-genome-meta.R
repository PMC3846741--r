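test_that("base frequencies use called bases only, case-insensitively", {
  fa <- write_test_fasta(list(s1 = "ACGTACGTACGT"), "uniform")
  meta <- compile_genome_meta(fa, build_label = "uniform")
  expect_equal(unlist(meta$genome_base_freq$freq),
               c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_identical(meta$genome_base_freq$ambiguous, 0L)

  fa2 <- write_test_fasta(list(s1 = "NNaAcC"), "ambig")
  meta2 <- compile_genome_meta(fa2, build_label = "ambig")
  f <- unlist(meta2$genome_base_freq$freq)
  expect_equal(unname(f["A"]), 0.5)
  expect_equal(unname(f["C"]), 0.5)
  expect_identical(meta2$genome_base_freq$ambiguous, 2L)
  expect_identical(meta2$genome_base_freq$called, 4L)
})

test_that("per-chromosome called-base frequencies sum to one", {
  meta <- toy_genome()$meta
  for (ch in names(meta$chrom_base_freq)) {
    expect_equal(sum(unlist(meta$chrom_base_freq[[ch]]$freq)), 1,
                 tolerance = 1e-9)
  }
})

test_that("exon intervals and derived intron/intergenic partition the genome", {
  g <- toy_genome()
  meta <- g$meta
  expect_setequal(names(meta$features), c("exon", "intron", "intergenic"))
  class_len <- vapply(meta$features, function(df) {
    sum(df$end - df$start + 1)
  }, numeric(1))
  expect_equal(sum(class_len), sum(unlist(meta$chrom_lengths)))
  # classes are disjoint
  for (a in names(meta$features)) {
    for (b in setdiff(names(meta$features), a)) {
      ga <- meta$features[[a]]
      gb <- meta$features[[b]]
      for (i in seq_len(nrow(ga))) {
        overlap <- gb$chrom == ga$chrom[i] & gb$start <= ga$end[i] &
          gb$end >= ga$start[i]
        expect_false(any(overlap))
      }
    }
  }
  # toy layout: 8 genes x 3 exons x 300 bp
  expect_equal(unname(class_len["exon"]), 8 * 3 * 300)
})

test_that("feature_of applies exon > intron > intergenic priority", {
  meta <- toy_genome()$meta
  ex <- meta$features$exon[1, ]
  expect_identical(feature_of(meta, ex$chrom, ex$start), "exon")
  intr <- meta$features$intron[1, ]
  expect_identical(feature_of(meta, intr$chrom, intr$start), "intron")
  ig <- meta$features$intergenic[1, ]
  expect_identical(feature_of(meta, ig$chrom, ig$start), "intergenic")
  expect_error(feature_of(meta, "chrX", 1), class = "bamdigest_UnknownChromosome")
})

test_that("annotation naming unknown sequences is rejected", {
  fa <- write_test_fasta(list(s1 = strrep("ACGT", 300)), "mismatch")
  gff <- file.path(fixture_dir(), "bad.gff3")
  writeLines(c("##gff-version 3",
               "sOther\ttoy\texon\t10\t50\t.\t+\t.\tID=x"), gff)
  expect_error(compile_genome_meta(fa, gff),
               class = "bamdigest_AnnotationChromMismatch")
})

test_that("BED annotation classes pass through with coordinate conversion", {
  fa <- write_test_fasta(list(s1 = strrep("ACGT", 300)), "bedded")
  bed <- file.path(fixture_dir(), "cls.bed")
  # BED is 0-based half-open: [99, 199) -> 1-based [100, 199]
  writeLines("s1\t99\t199\tpromoter", bed)
  meta <- compile_genome_meta(fa, bed)
  expect_true("promoter" %in% names(meta$features))
  expect_identical(meta$features$promoter$start, 100L)
  expect_identical(meta$features$promoter$end, 199L)
  expect_identical(feature_of(meta, "s1", 150), "promoter")
  expect_identical(feature_of(meta, "s1", 250), "intergenic")
})

test_that("store round trip is lossless and compile is idempotent", {
  g <- toy_genome()
  path <- file.path(fixture_dir(), "toy.gmeta.json")
  save_genome_meta(g$meta, path)
  loaded <- load_genome_meta(path)
  expect_equal(unlist(loaded$chrom_lengths), unlist(g$meta$chrom_lengths))
  expect_equal(unlist(loaded$genome_base_freq$freq),
               unlist(g$meta$genome_base_freq$freq))
  for (nm in names(g$meta$features)) {
    expect_equal(loaded$features[[nm]], g$meta$features[[nm]])
  }
  meta2 <- compile_genome_meta(g$fasta, g$annotation, "toy")
  expect_equal(meta2, g$meta)
})

test_that("corrupt and future-version stores raise distinct errors", {
  path <- file.path(fixture_dir(), "trunc.gmeta.json")
  save_genome_meta(toy_genome()$meta, path)
  full <- readLines(path)
  writeLines(full[1:(length(full) %/% 2)], path)
  expect_error(load_genome_meta(path), class = "bamdigest_CorruptStore")

  path2 <- file.path(fixture_dir(), "future.gmeta.json")
  save_genome_meta(toy_genome()$meta, path2)
  txt <- readLines(path2)
  txt <- sub('"version": 1', '"version": 99', txt)
  writeLines(txt, path2)
  expect_error(load_genome_meta(path2), class = "bamdigest_VersionMismatch")

  expect_error(load_genome_meta(write_test_fasta(list(s = "ACGT"), "notjson")),
               class = "bamdigest_CorruptStore")
})

test_that("empty FASTA is rejected", {
  path <- file.path(fixture_dir(), "empty.fa")
  writeLines(character(0), path)
  expect_error(compile_genome_meta(path), class = "bamdigest_EmptyFasta")
})
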