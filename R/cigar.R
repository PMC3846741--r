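## CIGAR accounting.
##
## The CIGAR string is a run-length encoding of the base-pair alignment:
## M/=/X consume read and reference, I/S consume read only, D/N consume
## reference only, H/P consume neither. "75M" is a 75-base gapless
## alignment; "20M1D55M" is a 75-base read spanning 76 reference bases
## across a single-base deletion.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
READ_OPS <- c("M", "I", "S", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")

#' Summarize a CIGAR string
#'
#' Tallies aligned bases per CIGAR operation class and derives the read
#' length (sum of read-consuming operations M, I, S, =, X) and the
#' reference span (sum of reference-consuming operations M, D, N, =, X).
#'
#' @param cigar a single CIGAR string, e.g. `"20M1D55M"`, or `"*"`
#'   (unavailable), which yields an all-zero summary.
#' @return an object of class `cigar_summary`: a list with
#'   `bases_by_op` (named integer vector over the nine operation
#'   classes), `read_len`, and `ref_span`.
#' @examples
#' cigar_stats("75M")$ref_span       # 75
#' cigar_stats("20M1D55M")$read_len  # 75
#' @export
cigar_stats <- function(cigar) {
  if (!is.character(cigar) || length(cigar) != 1L || is.na(cigar)) {
    bd_stop("MalformedCigar", "cigar must be a single non-NA character string")
  }
  counts <- stats::setNames(integer(length(CIGAR_OPS)), CIGAR_OPS)
  if (!identical(cigar, "*")) {
    m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
    tokens <- regmatches(cigar, list(m))[[1]]
    if (m[1] == -1L || paste(tokens, collapse = "") != cigar) {
      bd_stop("MalformedCigar", sprintf("not a valid CIGAR string: '%s'", cigar))
    }
    lens <- as.integer(sub("[MIDNSHP=X]$", "", tokens))
    ops <- sub("^[0-9]+", "", tokens)
    for (i in seq_along(ops)) counts[[ops[i]]] <- counts[[ops[i]]] + lens[i]
  }
  structure(
    list(
      bases_by_op = counts,
      read_len = sum(counts[READ_OPS]),
      ref_span = sum(counts[REF_OPS])
    ),
    class = "cigar_summary"
  )
}

#' @export
print.cigar_summary <- function(x, ...) {
  nz <- x$bases_by_op[x$bases_by_op > 0]
  cat("CIGAR summary: ",
      if (length(nz)) paste(names(nz), nz, sep = "=", collapse = " ") else "empty",
      "\n  read_len = ", x$read_len, ", ref_span = ", x$ref_span, "\n", sep = "")
  invisible(x)
}

## Vectorized CIGAR tally for many strings. Returns a matrix with one
## row per input and one column per op class, plus read_len/ref_span
## columns. Parses unique strings only: aligned data is dominated by a
## handful of CIGAR shapes, so this is orders of magnitude faster than
## a per-record parse.
cigar_table <- function(cigars) {
  u <- unique(cigars)
  mat <- matrix(0L, nrow = length(u), ncol = length(CIGAR_OPS),
                dimnames = list(NULL, CIGAR_OPS))
  for (i in seq_along(u)) {
    mat[i, ] <- cigar_stats(u[i])$bases_by_op
  }
  idx <- match(cigars, u)
  out <- mat[idx, , drop = FALSE]
  cbind(out,
        read_len = as.integer(rowSums(out[, READ_OPS, drop = FALSE])),
        ref_span = as.integer(rowSums(out[, REF_OPS, drop = FALSE])))
}

## Reference span of each CIGAR (vectorized).
cigar_ref_span <- function(cigars) {
  unname(cigar_table(cigars)[, "ref_span"])
}
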