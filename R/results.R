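## Orchestration: run the full digest of a BAM file into a single
## structured results bundle, persist it as JSON, and reload it. The
## statistics layer and the report template communicate only through
## this bundle, so a report can be re-rendered from a saved bundle
## without touching the BAM again.

#' Digest configuration
#'
#' @param sample_size reads drawn for per-base statistics (default
#'   [default_sample_size()], 1e5)
#' @param seed subsampling seed (default 17, so repeated digests of
#'   one file are identical)
#' @param filter a [bam_filter()]
#' @param depth_thresholds depth cutoffs for the coverage table
#' @param quality_cutoffs Phred cutoffs for the quality table
#' @param mapq_cutoffs mapq cutoffs for the mapping table
#' @param k k-mer length for read-end composition
#' @param max_insert insert-size cap (bp)
#' @param bin_width depth-landscape bin width; `NULL` = automatic
#' @param rules alert rules (list of [alert_rule()])
#' @return a `digest_config` list
#' @export
digest_config <- function(sample_size = default_sample_size(),
                          seed = 17L,
                          filter = bam_filter(),
                          depth_thresholds = c(1L, 5L, 10L, 20L, 30L, 50L, 100L),
                          quality_cutoffs = c(10L, 20L, 30L, 40L),
                          mapq_cutoffs = c(1L, 10L, 20L, 30L, 60L, 70L),
                          k = 5L,
                          max_insert = 10000L,
                          bin_width = NULL,
                          rules = default_alert_rules()) {
  structure(
    list(sample_size = as.integer(sample_size), seed = as.integer(seed),
         filter = filter, depth_thresholds = depth_thresholds,
         quality_cutoffs = quality_cutoffs, mapq_cutoffs = mapq_cutoffs,
         k = as.integer(k), max_insert = as.integer(max_insert),
         bin_width = bin_width, rules = rules),
    class = "digest_config"
  )
}

#' Run the full digest of a BAM file
#'
#' Orchestrates validation, the full-pass location scan, the seeded
#' read subsample, every statistic, and the alert rules into one
#' bundle. Deterministic given (inputs, config): provenance timestamps
#' come from the input file, not the wall clock.
#'
#' @param bam path to a coordinate-sorted, indexed BAM
#' @param meta a `genome_meta` for the reference the BAM was mapped to
#' @param config a [digest_config()]
#' @return a `results_bundle` with sections provenance, summary,
#'   depth, quality, mapping, composition, alerts
#' @export
build_results <- function(bam, meta, config = digest_config()) {
  stopifnot(inherits(meta, "genome_meta"))
  info <- validate_bam(bam)
  table <- scan_mapping_locations(bam, filter = config$filter)
  sample <- sample_full_records(bam, n = config$sample_size,
                                seed = config$seed, filter = config$filter)

  profile <- compute_depth(table, meta, bin_width = config$bin_width)
  depth_section <- list(
    total_depth = profile$total_depth,
    genome_length = profile$genome_length,
    mean_depth = profile$total_depth / profile$genome_length,
    landscape = profile$landscape,
    thresholds = depth_threshold_table(profile, config$depth_thresholds),
    per_chromosome = chromosome_mean_depth(profile),
    per_feature = if (length(meta$features)) {
      feature_mean_depth(profile, meta)
    } else {
      NULL
    }
  )

  qual <- quality_summary(sample, config$quality_cutoffs)
  posq <- positional_quality(sample)
  quality_section <- list(
    histogram = qual$histogram,
    thresholds = qual$thresholds,
    mean_quality = qual$mean_quality,
    median_quality = qual$median_quality,
    total_sampled_bases = qual$total_bases,
    positional = list(
      position = seq_along(posq$mean),
      mean = posq$mean,
      median = posq$median,
      n_reads = unname(posq$n_reads)
    )
  )

  strand <- strand_fractions(table)
  mapping_section <- list(
    flag = as.list(flag_summary(bam)),
    mapq = mapq_summary(table, config$mapq_cutoffs),
    mismatch = local({
      mm <- mismatch_summary(sample)
      mm$base_fractions <- as.list(mm$base_fractions)
      mm
    }),
    duplication = duplication_histogram(table),
    insert = insert_size_summary(sample, config$max_insert),
    strand = list(forward = unname(strand["forward"]),
                  reverse = unname(strand["reverse"]),
                  max_fraction = unname(max(strand)))
  )

  composition_section <- base_composition(sample, meta, k = config$k)

  mean_read_len <- mean(nchar(sample$records$seq))
  bundle <- structure(
    list(
      provenance = list(
        tool = "bamdigest",
        version = as.character(utils::packageVersion("bamdigest")),
        bam = basename(bam),
        bam_path = bam,
        bam_mtime = format(file.mtime(bam), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
        build_label = meta$provenance$build_label,
        seed = sample$seed,
        sample_size = sample$requested_n,
        n_sampled = nrow(sample$records)
      ),
      summary = list(
        total_reads = nrow(table),
        total_alignments = attr(table, "total_alignments"),
        filtered_out = attr(table, "filtered_out"),
        mean_read_length = mean_read_len,
        est_total_bases = mean_read_len * nrow(table),
        mean_quality = qual$mean_quality,
        mean_depth = depth_section$mean_depth,
        mean_mapq = mapping_section$mapq$mean_mapq,
        gc_fraction = composition_section$gc$mean
      ),
      depth = depth_section,
      quality = quality_section,
      mapping = mapping_section,
      composition = composition_section,
      alerts = list()
    ),
    class = "results_bundle"
  )
  bundle$alerts <- evaluate_alerts(bundle, config$rules)
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("bamdigest results for '", x$provenance$bam, "' (build ",
      x$provenance$build_label, ")\n", sep = "")
  cat("  reads: ", x$summary$total_reads,
      "; mean depth: ", signif(x$summary$mean_depth, 4),
      "; mean quality: ", signif(x$summary$mean_quality, 4), "\n", sep = "")
  cat("  alerts: ", length(x$alerts), "\n", sep = "")
  invisible(x)
}

#' Serialize a results bundle to JSON
#' @param results a `results_bundle`
#' @param path output path
#' @return `path`, invisibly
#' @export
serialize_results <- function(results, path) {
  stopifnot(inherits(results, "results_bundle"))
  json <- jsonlite::toJSON(unclass(results), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null",
                           dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' Load a results bundle from JSON
#' @param path path written by [serialize_results()]
#' @return a `results_bundle`
#' @export
load_results <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) bd_stop("CorruptResults", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$provenance$tool, "bamdigest")) {
    bd_stop("CorruptResults",
            sprintf("'%s' is not a bamdigest results bundle", path))
  }
  structure(obj, class = "results_bundle")
}
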