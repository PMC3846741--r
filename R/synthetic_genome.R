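## Toy reference genomes with known composition and feature layout.
## Everything is generated programmatically so tests and examples need
## no external data.

#' Generate a toy reference genome with annotation
#'
#' Writes a FASTA with random sequence of specified base weights and a
#' GFF3 annotation with a regular gene/exon layout, then compiles the
#' genome metadata store. Deterministic under `seed`.
#'
#' @param dir output directory (created if needed)
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param base_weights sampling weights for A, C, G, T
#' @param genes_per_chrom number of evenly spaced genes per chromosome
#'   (0 disables annotation)
#' @param gene_length length of each gene span (bp)
#' @param exons_per_gene exons per gene, evenly spaced within the gene
#' @param exon_length length of each exon (bp)
#' @param seed integer seed
#' @param build_label label recorded in the metadata provenance
#' @return list with `fasta`, `annotation` (paths) and `meta`
#'   (a `genome_meta`)
#' @export
generate_toy_genome <- function(dir,
                                chrom_lengths = c(chr1 = 60000L, chr2 = 40000L),
                                base_weights = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                                genes_per_chrom = 4L,
                                gene_length = 3000L,
                                exons_per_gene = 3L,
                                exon_length = 300L,
                                seed = 1L,
                                build_label = "toy") {
  stopifnot(all(chrom_lengths >= 1000L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(build_label, ".fa"))
  seqs <- with_seed(seed, {
    lapply(chrom_lengths, function(L) {
      paste(sample(BASES, L, replace = TRUE, prob = base_weights),
            collapse = "")
    })
  })
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- names(chrom_lengths)
  Biostrings::writeXStringSet(dna, fasta)

  annotation <- NULL
  if (genes_per_chrom > 0L) {
    annotation <- file.path(dir, paste0(build_label, ".gff3"))
    lines <- c("##gff-version 3")
    gid <- 0L
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      spacing <- L %/% (genes_per_chrom + 1L)
      stopifnot(spacing > gene_length)
      for (g in seq_len(genes_per_chrom)) {
        gid <- gid + 1L
        gs <- g * spacing
        ge <- gs + gene_length - 1L
        lines <- c(lines, sprintf(
          "%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=gene%d", ch, gs, ge, gid))
        estep <- gene_length %/% exons_per_gene
        for (e in seq_len(exons_per_gene)) {
          es <- gs + (e - 1L) * estep
          ee <- es + exon_length - 1L
          lines <- c(lines, sprintf(
            "%s\ttoy\texon\t%d\t%d\t.\t+\t.\tParent=gene%d", ch, es, ee, gid))
        }
      }
    }
    writeLines(lines, annotation)
  }

  meta <- compile_genome_meta(fasta, annotation, build_label)
  list(fasta = fasta, annotation = annotation, meta = meta)
}
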