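## Internal helpers: classed conditions, seed derivation, small numerics.

#' Signal a classed bamdigest error
#'
#' All package errors carry a machine-readable class
#' (`bamdigest_<id>`) so callers and tests can distinguish failure
#' modes without parsing messages.
#'
#' @param id short error identifier, e.g. "MissingIndex"
#' @param message human-readable message
#' @param ... fields attached to the condition
#' @noRd
bd_stop <- function(id, message, ...) {
  cond <- structure(
    class = c(paste0("bamdigest_", id), "bamdigest_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Derive a child seed from a master seed
#'
#' Keeps derived seeds strictly below 2^31 so they remain valid R
#' integers. Deterministic and collision-poor for the small stream
#' counts used here (reps, reads, chromosomes).
#' @noRd
bd_child_seed <- function(seed, stream) {
  (as.double(seed) * 69069 + as.double(stream) * 104729 + 12345) %% 2147483587
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards so library sampling never perturbs user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483587))
  expr
}

## Weighted median of values with integer counts (used for positional
## quality summaries where scores arrive as histograms).
weighted_median <- function(values, counts) {
  stopifnot(length(values) == length(counts))
  keep <- counts > 0
  values <- values[keep]
  counts <- counts[keep]
  if (length(values) == 0L) return(NA_real_)
  ord <- order(values)
  values <- values[ord]
  counts <- counts[ord]
  cum <- cumsum(counts)
  total <- cum[length(cum)]
  lo <- values[which(cum >= total / 2)[1]]
  hi <- values[which(cum >= total / 2 + 0.5)[1]]
  (lo + hi) / 2
}

## Phred-33 decoding of a QUAL string into integer scores.
qual_to_scores <- function(qual) {
  if (is.na(qual) || identical(qual, "*")) return(integer(0))
  utf8ToInt(qual) - 33L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
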