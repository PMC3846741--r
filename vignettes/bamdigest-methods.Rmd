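---
title: "bamdigest: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bamdigest: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `bamdigest` computes what it reports, which
knobs matter, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite does not
itself compute.

## The statistical model of a digest

A digest treats a BAM file as two populations:

1. the set of **counted alignments** — records passing the inclusion
   filter (mapped, primary, non-supplementary; duplicates retained) —
   whose *per-read* fields (position, strand, MAPQ, CIGAR span) are
   cheap enough to load in full; and
2. the same set viewed through its **per-base** fields (SEQ, QUAL,
   CIGAR detail, TLEN), which dominate file size and are summarized
   from a uniform random subsample of n reads.

Every subsample-based statistic is a ratio or mean of per-read
contributions, so it is an unbiased estimator of its full-data
counterpart, with Monte-Carlo error shrinking as 1/sqrt(n). The
`run_convergence()` module makes that premise checkable per file:
repeated seeded subsamples at increasing sizes must narrow onto the
global value. On desk-scale synthetic data (and in the acceptance
suite at 10^6 reads) the inter-quartile range of the estimates is
non-increasing in subsample size and the largest size brackets the
global value; n = 10^5 reproduces global scalar statistics closely,
which is why `default_sample_size()` is 10^5.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `sample_size` | 100000 | reads | smallest size at which resampled statistics are both precise and consistent |
| `seed` | 17 | — | fixed so repeated digests of one file are byte-identical |
| `depth_thresholds` | 1, 5, 10, 20, 30, 50, 100 | × coverage | conventional depth milestones for variant calling / expression work |
| `quality_cutoffs` | 10, 20, 30, 40 | Phred | decade cutoffs; Q30 ⇔ error probability 0.001 |
| `mapq_cutoffs` | 1, 10, 20, 30, 60, 70 | MAPQ | spans the scales used by common aligners (bwa caps at 60, others at 70) |
| `k` | 5 | bp | read-end k-mer length; long enough to expose adapter/primer signatures, short enough to keep tables dense |
| `max_insert` | 10000 | bp | |TLEN| cap excluding translocation-scale artifacts from the histogram (excluded count is reported) |
| landscape bin width | len/500 floored to 1 kb, min 1 kb | bp | low-resolution by design: the landscape is an index for spotting large anomalies, not a browser track |

Alert rules default to: uncalled-base frequency **> 0.5%**, and
**> 55%** of reads on one strand. Comparisons are strict, so exact
boundary values do not fire. Rules are extensible via a JSON config
(`alert_rules_from_json()`); JSON was chosen over YAML because the
supported toolchain carries no YAML parser, and the rule vocabulary
(dotted metric path, comparator, threshold, message) is identical.

## Conventions and numerical choices

* **Coordinates** are SAM 1-based inclusive everywhere internally; BED
  input is converted on import.
* **Strand** comes from FLAG bit 0x10 only; mate strand is ignored.
* **Inclusion filter**: unmapped (0x4), secondary (0x100) and
  supplementary (0x800) records are excluded from the mapping table
  and the subsample; duplicates (0x400) are *included*, because
  duplication is reported as a statistic rather than silently removed.
  The FLAG tabulation always sees every record in the file.
* **Pileup** is exact: each alignment contributes its CIGAR reference
  span (M, D, N, =, X) via a difference array, O(reads + genome) per
  chromosome. The invariant Σdepth = Σref_span is asserted in tests on
  every synthetic input. Storing MAPQ and ref_span in the full pass
  (beyond the minimal chromosome/position/strand triple) is a
  deliberate trade: a modest memory overhead buys an exact rather than
  read-length-approximated pileup; a `minimal` mode drops the columns.
* **Reservoir sampling** (Algorithm R, vectorized per chunk) gives
  every passing read inclusion probability min(1, n/N) without
  replacement in a single pass; sampling with a fixed seed is
  deterministic, and tests verify uniformity by chi-square over 200
  repeated draws. Whether the original procedure sampled with or
  without replacement is unspecified in the literature this follows;
  without replacement was chosen as the variant whose n = N limit
  degenerates to the exact full-data statistic.
* **Sequencing orientation**: positional quality and composition
  statistics reverse(-complement) reverse-strand records back to read
  orientation first. The alternative (reference orientation) was
  rejected because start-of-read artifacts — primer contamination,
  biased priming, quality ramp-in — only line up across strands in
  read orientation.
* **CIGAR normalization**: M, I and S base counts are fractions of
  total read bases; D bases consume no read bases and are normalized
  by aligned reference span instead.
* **Duplicate key** is (chromosome, leftmost position, strand), with
  no 5′-clip adjustment — duplication here means "multiple reads at
  one mapping location", not a Picard-style library-duplicate call.
* **Expected base frequency** is strand-symmetrized from the genome
  store: E(A)=E(T)=(fA+fT)/2, E(C)=E(G)=(fC+fG)/2, because reads
  sample both strands of a double-stranded template.
* **Positional medians** on tied score histograms use the midpoint of
  the lower/upper weighted medians, so a flat histogram yields the
  conventional half-integer value.
* **Feature priority** when annotation classes overlap is exon >
  other explicit classes > intron > intergenic; classes are made
  disjoint at compile time, so they partition each chromosome exactly
  (asserted in tests). Introns are derived as gene span minus exons
  when gene features exist; intergenic is the complement of gene
  spans. Classes beyond exon/intron/intergenic (e.g. BED-named
  promoters) pass through but are not derived.
* **Degenerate inputs**: an empty BAM digests to zero-row tables; a
  single-end BAM marks the insert-size section *absent* rather than
  zero; all-`*` QUAL raises `MissingQuality`; alignments extending
  past the metadata's chromosome ends raise
  `PositionBeyondChromosome` (the canonical symptom of digesting
  against the wrong genome build).

## Reporting layer

The statistics layer and the renderer communicate only through the
results bundle: `render_report()` is a pure function of the bundle,
enforced in tests by rendering from a re-loaded JSON bundle and
requiring byte-identical output. Timestamps in the report come from
the input file's modification time recorded in provenance, never from
the render clock. The HTML report carries the seven sections in fixed
order (depth landscape, summary, coverage, quality, mapping, base
frequency, alerts) with deterministic inline-SVG figures. PDF export
is not bundled — the environment carries no PDF backend — so
`format = "pdf"` raises `RendererUnavailable` with an HTML fallback
instruction.

## What the synthetic generator emulates

`generate_synthetic_bam()` produces sorted, indexed BAMs in which
**every reported statistic has a controlled cause**: read positions
(optionally biased into a feature class), strand fractions, MAPQ
distribution (default ~95% at the aligner-best score 70), a linear
quality-decay model (default start 35, 0.05/bp, sd 2, clamped to
[2, 41] — chosen once to mirror real short-read data where most bases
score near Q30 and quality degrades toward read ends), per-base N
substitution, per-read soft-clip/insertion/deletion CIGARs
(single-end specs only), location-copying duplicates, and FR pairs
with Gaussian fragment lengths (default mean 262.6 bp, sd 60 — a
typical short-insert library, and the numeric instance the resampling
experiment is exercised at). Reads are otherwise error-free copies of
the reference, so CIGAR classes fully determine mismatch statistics
and observed composition must match the genome.

The truth record stores *realized* quantities (exact counts,
multiplicity histograms, per-position quality sums, fragment means),
not just the requested rates; exact statistics are compared exactly
and sampled ones within 3 Monte-Carlo standard errors. One subtlety
is duplication: independent random origins collide by chance on a
finite genome, so the realized duplicate fraction exceeds the
requested rate. The generator therefore also records the requested
duplicate count, which is binomially checked, while the multiplicity
histogram is checked exactly.

What the generator does **not** emulate: platform error profiles,
base-call substitution errors, PCR chimeras, GC-dependent coverage
bias, or reference gaps. A green test therefore establishes that the
*accounting* is correct — not that the digest's thresholds are
well-calibrated for any particular instrument's pathology.

## Known limitations

* CRAM, remote streaming, and on-the-fly sorting of unsorted BAMs are
  out of scope; inputs must be local, coordinate-sorted, indexed BAMs.
* Mismatch reporting is CIGAR-class based; MD/NM-tag or
  reference-comparison mismatch detection is deliberately not
  implemented.
* The per-base depth vector is materialized per chromosome, which is
  comfortable for genomes up to hundreds of megabases per chromosome
  but would need windowed accumulation for exotic multi-gigabase
  chromosomes.
* Multi-BAM comparison and region drill-down are out of scope.
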