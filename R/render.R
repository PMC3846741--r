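## HTML report renderer: a pure function of the results bundle. Two
## renders of the same bundle are byte-identical — all timestamps come
## from the bundle's provenance, and figures are deterministic inline
## SVG built from the bundle's tables.

fmt_num <- function(x, digits = 4) {
  out <- as.character(x)
  v <- suppressWarnings(as.numeric(x))
  ok <- is.finite(v)
  out[ok] <- vapply(v[ok], function(val) {
    if (val == round(val) && abs(val) < 1e15) {
      format(val, big.mark = ",", scientific = FALSE)
    } else {
      format(signif(val, digits), scientific = FALSE)
    }
  }, character(1))
  out
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, caption = NULL) {
  if (is.null(df) || !NROW(df)) return("<p><em>no data</em></p>")
  df <- as.data.frame(df)
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body <- apply(df, 1, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(fmt_num(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  paste0("<table>",
         if (!is.null(caption)) paste0("<caption>", caption, "</caption>"),
         head_row, paste(body, collapse = ""), "</table>")
}

## simple bar chart: heights scaled into a fixed-size SVG viewport
svg_bars <- function(x, y, width = 640, height = 160, label = "") {
  if (!length(y) || all(!is.finite(y)) || max(y, na.rm = TRUE) <= 0) {
    return("<p><em>no data</em></p>")
  }
  n <- length(y)
  bw <- width / n
  ymax <- max(y, na.rm = TRUE)
  bars <- vapply(seq_len(n), function(i) {
    h <- if (is.finite(y[i])) y[i] / ymax * (height - 10) else 0
    sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="#4878a8"/>',
            (i - 1) * bw, height - h, bw * 0.9, h)
  }, character(1))
  sprintf('<svg viewBox="0 0 %d %d" width="%d" height="%d" role="img" aria-label="%s">%s</svg>',
          width, height, width, height, label, paste(bars, collapse = ""))
}

## polyline over index positions
svg_line <- function(y, width = 640, height = 120, color = "#305070") {
  ok <- is.finite(y)
  if (!any(ok)) return("<p><em>no data</em></p>")
  ymax <- max(y[ok])
  ymin <- min(y[ok])
  span <- if (ymax > ymin) ymax - ymin else 1
  pts <- sprintf("%.2f,%.2f",
                 (seq_along(y) - 1) / max(length(y) - 1, 1) * width,
                 height - 5 - (y - ymin) / span * (height - 10))
  sprintf('<svg viewBox="0 0 %d %d" width="%d" height="%d"><polyline points="%s" fill="none" stroke="%s" stroke-width="1.5"/></svg>',
          width, height, width, height, paste(pts[ok], collapse = " "), color)
}

REPORT_SECTIONS <- c(
  "depth-landscape" = "Sequencing depth landscape",
  "summary-statistics" = "Summary statistics",
  "read-count-coverage" = "Read count and sequencing coverage",
  "sequencing-quality" = "Sequencing quality",
  "genome-mapping" = "Reference genome mapping",
  "base-frequency" = "Base frequency",
  "alerts" = "Alerts"
)

## normalize alerts loaded from JSON (data.frame) or built in memory (list)
alerts_as_list <- function(alerts) {
  if (is.data.frame(alerts)) {
    lapply(seq_len(nrow(alerts)), function(i) as.list(alerts[i, ]))
  } else {
    alerts
  }
}

section_depth_landscape <- function(x) {
  ls <- as.data.frame(x$depth$landscape)
  chunks <- lapply(split(ls, ls$chrom), function(g) {
    paste0("<h3>", html_escape(g$chrom[1]), "</h3>",
           svg_line(g$mean_depth,
                    color = "#305070"))
  })
  paste0("<p>Mean depth in fixed-width bins along each chromosome; ",
         "use it to spot large regions of unusual coverage.</p>",
         paste(unlist(chunks[order(names(chunks))]), collapse = ""))
}

section_summary <- function(x) {
  s <- x$summary
  df <- data.frame(
    statistic = c("Counted reads", "Total alignments in file",
                  "Filtered-out alignments", "Mean read length (bp)",
                  "Estimated total bases", "Mean base quality",
                  "Mean depth", "Mean mapping quality", "Mean GC fraction"),
    value = fmt_num(c(s$total_reads, s$total_alignments, s$filtered_out,
                      s$mean_read_length, s$est_total_bases, s$mean_quality,
                      s$mean_depth, s$mean_mapq, s$gc_fraction))
  )
  html_table(df)
}

section_coverage <- function(x) {
  out <- paste0("<h3>Genome fraction at depth thresholds</h3>",
                html_table(x$depth$thresholds))
  if (!is.null(x$depth$per_feature)) {
    out <- paste0(out, "<h3>Mean depth by genomic feature</h3>",
                  html_table(x$depth$per_feature))
  }
  paste0(out, "<h3>Mean depth by chromosome</h3>",
         html_table(x$depth$per_chromosome))
}

section_quality <- function(x) {
  q <- x$quality
  paste0(
    "<h3>Score distribution</h3>",
    svg_bars(q$histogram$score, q$histogram$count, label = "quality histogram"),
    html_table(q$thresholds, "Fraction of bases at or above quality cutoffs"),
    "<h3>Quality by read position</h3>",
    "<p>Mean (solid) per position, in sequencing orientation.</p>",
    svg_line(as.numeric(q$positional$mean)),
    html_table(data.frame(position = q$positional$position,
                          mean = q$positional$mean,
                          median = q$positional$median,
                          reads = q$positional$n_reads)[
                            seq(1, length(q$positional$position),
                                by = max(1, length(q$positional$position) %/% 20)), ],
               "Positional quality (thinned)")
  )
}

section_mapping <- function(x) {
  m <- x$mapping
  flag_df <- data.frame(category = names(m$flag),
                        count = unlist(m$flag, use.names = FALSE))
  out <- paste0(
    "<h3>FLAG categories</h3>", html_table(flag_df),
    "<h3>Mapping quality</h3>",
    html_table(m$mapq$thresholds, "Fraction of reads at or above mapq cutoffs"),
    "<h3>CIGAR base classes</h3>",
    html_table(data.frame(class = names(m$mismatch$base_fractions),
                          fraction = unlist(m$mismatch$base_fractions,
                                            use.names = FALSE))),
    sprintf("<p>Fraction of reads with any insertion, deletion or soft clip: %s</p>",
            fmt_num(m$mismatch$reads_with_indel_or_clip)),
    "<h3>Duplicate mapping</h3>",
    html_table(m$duplication,
               "Reads per location (multiplicity) vs number of locations"),
    "<h3>Strand balance</h3>",
    html_table(data.frame(strand = c("forward", "reverse"),
                          fraction = c(m$strand$forward, m$strand$reverse)))
  )
  if (isTRUE(m$insert$absent)) {
    out <- paste0(out, "<h3>Insert size</h3>",
                  "<p><em>absent: no properly paired reads</em></p>")
  } else {
    out <- paste0(
      out, "<h3>Insert size</h3>",
      sprintf("<p>mean %s bp, median %s bp over %s pairs (%s beyond cap excluded)</p>",
              fmt_num(m$insert$mean), fmt_num(m$insert$median),
              fmt_num(m$insert$n_pairs), fmt_num(m$insert$n_excluded)),
      svg_bars(m$insert$histogram$insert_size, m$insert$histogram$count,
               label = "insert size histogram")
    )
  }
  out
}

section_composition <- function(x) {
  cc <- x$composition
  obs <- unlist(cc$observed_freq)
  exp <- unlist(cc$expected_freq)
  paste0(
    sprintf("<p>Uncalled (N) base fraction: %s; reads containing any N: %s</p>",
            fmt_num(cc$n_base_fraction), fmt_num(cc$fraction_reads_with_n)),
    "<h3>Observed vs expected base frequency</h3>",
    html_table(data.frame(base = names(obs), observed = unname(obs),
                          expected = unname(exp[names(obs)]),
                          ratio = unname(obs / exp[names(obs)]))),
    "<h3>Per-read GC</h3>",
    svg_bars(cc$gc$histogram$bin_low, cc$gc$histogram$count,
             label = "GC histogram"),
    sprintf("<p>mean GC fraction %s</p>", fmt_num(cc$gc$mean)),
    "<h3>Base frequency at read start</h3>",
    html_table(cc$start_base_freq),
    "<h3>Base frequency at read end</h3>",
    html_table(cc$end_base_freq),
    sprintf("<h3>Most frequent %d-mers at read start</h3>", cc$k),
    html_table(cc$start_kmers),
    sprintf("<h3>Most frequent %d-mers at read end</h3>", cc$k),
    html_table(cc$end_kmers)
  )
}

section_alerts <- function(x) {
  alerts <- alerts_as_list(x$alerts)
  if (!length(alerts)) {
    return("<p>No alerts: all screened metrics are within limits.</p>")
  }
  items <- vapply(alerts, function(a) {
    sprintf("<li><strong>%s</strong>: %s</li>", html_escape(a$rule_id),
            html_escape(a$message))
  }, character(1))
  paste0("<ul>", paste(items, collapse = ""), "</ul>")
}

#' Render a results bundle as a sectioned HTML report
#'
#' The report contains, in order: depth landscape, summary statistics,
#' read count and coverage, sequencing quality, reference genome
#' mapping, base frequency, and alerts, with a linked table of
#' contents. Rendering reads nothing but the bundle, so a report can
#' be regenerated from a saved JSON bundle.
#'
#' @param results a `results_bundle` (fresh or loaded)
#' @param path output file path
#' @param format `"html"` (always available) or `"pdf"` (no PDF
#'   backend is bundled; an error with fallback instructions is
#'   raised)
#' @return `path`, invisibly
#' @export
render_report <- function(results, path, format = c("html", "pdf")) {
  format <- match.arg(format)
  if (format == "pdf") {
    bd_stop("RendererUnavailable",
            "no PDF backend is bundled; render to HTML and print to PDF from a browser")
  }
  renderers <- list(
    "depth-landscape" = section_depth_landscape,
    "summary-statistics" = section_summary,
    "read-count-coverage" = section_coverage,
    "sequencing-quality" = section_quality,
    "genome-mapping" = section_mapping,
    "base-frequency" = section_composition,
    "alerts" = section_alerts
  )
  toc <- paste0("<ol>", paste(sprintf('<li><a href="#%s">%s</a></li>',
                                      names(REPORT_SECTIONS),
                                      REPORT_SECTIONS), collapse = ""), "</ol>")
  sections <- vapply(names(REPORT_SECTIONS), function(id) {
    sprintf('<section id="%s"><h2>%s</h2>%s</section>',
            id, REPORT_SECTIONS[[id]], renderers[[id]](results))
  }, character(1))
  pv <- results$provenance
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>bamdigest report: %s</title>", html_escape(pv$bam)),
    "<style>body{font-family:sans-serif;max-width:960px;margin:auto;padding:1em;}",
    "table{border-collapse:collapse;margin:0.5em 0;}",
    "td,th{border:1px solid #999;padding:2px 8px;text-align:right;}",
    "th{background:#eee;}caption{caption-side:top;font-style:italic;}",
    "</style></head><body>",
    sprintf("<h1>bamdigest report: %s</h1>", html_escape(pv$bam)),
    sprintf("<p>tool version %s; genome build %s; BAM last modified %s; subsample %s reads (seed %s).</p>",
            html_escape(pv$version), html_escape(pv$build_label),
            html_escape(pv$bam_mtime), fmt_num(pv$sample_size),
            fmt_num(pv$seed)),
    "<nav>", toc, "</nav>",
    paste(sections, collapse = ""),
    "</body></html>"
  )
  writeLines(html, path)
  invisible(path)
}
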