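## Reference-genome metadata: chromosome lengths, base composition,
## and feature interval sets (exon / intron / intergenic), compiled
## from a FASTA plus optional GFF3/GTF or BED annotation. This is the
## digest's second input besides the BAM file, and the only place
## reference information enters the statistics.

GMETA_SCHEMA_VERSION <- 1L

## data.frame(chrom, start, end) -> GRanges with seqlengths
df_to_gr <- function(df, chrom_lengths) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = names(chrom_lengths)),
    ranges = IRanges::IRanges(df$start, df$end),
    seqlengths = chrom_lengths
  )
}

gr_to_df <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

base_freq_from_counts <- function(counts) {
  called <- sum(counts[c("A", "C", "G", "T")])
  freq <- if (called > 0) counts[c("A", "C", "G", "T")] / called else
    stats::setNames(rep(NA_real_, 4), c("A", "C", "G", "T"))
  list(
    freq = as.list(freq),
    called = as.integer(called),
    ambiguous = as.integer(counts[["other"]])
  )
}

read_annotation <- function(annotation, chrom_lengths) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", annotation)))
  gr <- rtracklayer::import(annotation)
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                 names(chrom_lengths))
  if (length(bad)) {
    bd_stop("AnnotationChromMismatch",
            sprintf("annotation names sequences absent from the FASTA: %s",
                    paste(bad, collapse = ", ")))
  }
  if (ext %in% c("gff", "gff3", "gtf")) {
    type <- as.character(gr$type)
    list(
      exon = gr[type == "exon"],
      gene = gr[type %in% c("gene", "transcript", "mRNA")]
    )
  } else if (ext == "bed") {
    ## BED name column carries the feature class; rtracklayer already
    ## converts 0-based half-open to 1-based inclusive
    cls <- if (!is.null(gr$name)) as.character(gr$name) else
      rep("feature", length(gr))
    split_gr <- split(gr, cls)
    as.list(split_gr)
  } else {
    bd_stop("AnnotationChromMismatch",
            sprintf("unsupported annotation format: '%s'", annotation))
  }
}

#' Compile a genome metadata store from FASTA and optional annotation
#'
#' Base frequencies are computed case-insensitively over called bases
#' (A/C/G/T); N and other IUPAC ambiguity codes are pooled into a
#' separate "ambiguous" count and excluded from the frequency
#' denominator. When gene features exist, introns are derived as gene
#' span minus exons and intergenic as the complement of gene spans;
#' the stored classes are made disjoint by priority (exon > other
#' classes > intron > intergenic) so they partition each chromosome.
#'
#' @param fasta path to a (optionally gzipped) FASTA file
#' @param annotation optional GFF3/GTF (feature column selects
#'   exon/gene) or BED (name column = feature class) file
#' @param build_label free-text label recorded in provenance
#' @return an object of class `genome_meta`
#' @export
compile_genome_meta <- function(fasta, annotation = NULL, build_label = "custom") {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) bd_stop("EmptyFasta", conditionMessage(e)))
  if (length(seqs) == 0L) {
    bd_stop("EmptyFasta", sprintf("no sequences in FASTA '%s'", fasta))
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chrom_lengths <- stats::setNames(Biostrings::width(seqs), names(seqs))

  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  rownames(af) <- names(seqs)
  chrom_base_freq <- lapply(names(seqs), function(ch) base_freq_from_counts(af[ch, ]))
  names(chrom_base_freq) <- names(seqs)
  genome_base_freq <- base_freq_from_counts(colSums(af))

  features <- list()
  if (!is.null(annotation)) {
    ann <- read_annotation(annotation, chrom_lengths)
    ann <- lapply(ann, function(gr) {
      GenomicRanges::trim(GenomicRanges::reduce(
        df_to_gr(gr_to_df(gr), chrom_lengths)))
    })
    exon <- if (!is.null(ann$exon)) ann$exon else
      df_to_gr(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0)), chrom_lengths)
    gene <- ann$gene
    classes <- list()
    if (length(exon)) classes$exon <- exon
    others <- setdiff(names(ann), c("exon", "gene"))
    for (nm in sort(others)) if (length(ann[[nm]])) classes[[nm]] <- ann[[nm]]
    if (!is.null(gene) && length(gene)) {
      intron <- GenomicRanges::setdiff(gene, exon)
      if (length(intron)) classes$intron <- intron
      classes$intergenic <- GenomicRanges::gaps(gene)
    } else {
      covered <- if (length(classes)) {
        GenomicRanges::reduce(do.call(c, unname(classes)))
      } else {
        df_to_gr(data.frame(chrom = character(0), start = integer(0),
                            end = integer(0)), chrom_lengths)
      }
      classes$intergenic <- GenomicRanges::gaps(covered)
    }
    ## gaps() emits per-strand ranges; collapse everything to '*'
    classes <- lapply(classes, function(gr) {
      gr <- gr[GenomicRanges::strand(gr) == "*"]
      GenomicRanges::reduce(gr)
    })
    ## make classes disjoint in priority order so they partition the genome
    taken <- NULL
    for (nm in names(classes)) {
      gr <- classes[[nm]]
      if (!is.null(taken)) gr <- GenomicRanges::setdiff(gr, taken)
      classes[[nm]] <- gr
      taken <- if (is.null(taken)) gr else GenomicRanges::reduce(c(taken, gr))
    }
    features <- lapply(classes, gr_to_df)
  }

  structure(
    list(
      version = GMETA_SCHEMA_VERSION,
      chrom_lengths = as.list(chrom_lengths),
      chrom_base_freq = chrom_base_freq,
      genome_base_freq = genome_base_freq,
      features = features,
      provenance = list(
        fasta = basename(fasta),
        annotation = if (is.null(annotation)) NULL else basename(annotation),
        build_label = build_label
      )
    ),
    class = "genome_meta"
  )
}

#' @export
print.genome_meta <- function(x, ...) {
  cat("Genome metadata '", x$provenance$build_label, "': ",
      length(x$chrom_lengths), " sequence(s), ",
      format(sum(unlist(x$chrom_lengths)), big.mark = ","), " bp\n", sep = "")
  if (length(x$features)) {
    cat("  feature classes:", paste(names(x$features), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Persist a genome metadata store as versioned JSON
#' @param meta a `genome_meta` object
#' @param path output path
#' @return `path`, invisibly
#' @export
save_genome_meta <- function(meta, path) {
  stopifnot(inherits(meta, "genome_meta"))
  json <- jsonlite::toJSON(unclass(meta), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a genome metadata store
#' @param path path written by [save_genome_meta()]
#' @return a `genome_meta` object
#' @export
load_genome_meta <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) bd_stop("CorruptStore", conditionMessage(e)))
  if (is.null(obj$version) || is.null(obj$chrom_lengths)) {
    bd_stop("CorruptStore", sprintf("'%s' is not a genome metadata store", path))
  }
  if (obj$version > GMETA_SCHEMA_VERSION) {
    bd_stop("VersionMismatch",
            sprintf("store schema version %s is newer than supported version %s",
                    obj$version, GMETA_SCHEMA_VERSION))
  }
  obj$features <- lapply(obj$features, function(df) {
    as.data.frame(df, stringsAsFactors = FALSE)
  })
  structure(obj, class = "genome_meta")
}

#' Feature class of a genomic position
#'
#' Returns the highest-priority feature class whose intervals contain
#' the position (classes are stored disjoint, in priority order
#' exon > other > intron > intergenic); `"intergenic"` if no class
#' contains it or no annotation was compiled.
#'
#' @param meta a `genome_meta` object
#' @param chrom chromosome name
#' @param pos 1-based position
#' @return feature class name (character scalar)
#' @export
feature_of <- function(meta, chrom, pos) {
  stopifnot(inherits(meta, "genome_meta"))
  len <- meta$chrom_lengths[[chrom]]
  if (is.null(len)) {
    bd_stop("UnknownChromosome", sprintf("unknown chromosome '%s'", chrom))
  }
  stopifnot(pos >= 1, pos <= len)
  for (nm in names(meta$features)) {
    df <- meta$features[[nm]]
    hit <- df$chrom == chrom & df$start <= pos & pos <= df$end
    if (any(hit)) return(nm)
  }
  "intergenic"
}
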