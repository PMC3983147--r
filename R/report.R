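## Decision logs and per-locus reports.

#' Write a decision log as TSV
#'
#' One row per locus: gene, endpoint, endpoint class, comma-joined node
#' path, and the per-node rationale booleans. Running the pipeline twice on
#' identical inputs produces byte-identical logs.
#'
#' @param decisions a named list of `reannotation_decision` objects
#'   (names = gene ids), or a single decision.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_decision_log <- function(decisions, path) {
  if (inherits(decisions, "reannotation_decision")) {
    decisions <- stats::setNames(list(decisions), "locus")
  }
  all_keys <- unique(unlist(lapply(decisions, function(d) names(d$rationale))))
  rows <- lapply(names(decisions), function(g) {
    d <- decisions[[g]]
    row <- data.frame(gene = g, endpoint = d$endpoint,
                      endpoint_class = d$endpoint_class,
                      node_path = paste(d$node_path, collapse = ","),
                      stringsAsFactors = FALSE)
    for (k in all_keys) {
      v <- d$rationale[[k]]
      row[[k]] <- if (is.null(v)) NA else v
    }
    row
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Render a human-readable per-locus report
#'
#' @param result a `pipeline_result`.
#' @param path optional file; when `NULL` the lines are returned.
#' @return character vector of report lines (invisibly when written).
#' @export
report_locus <- function(result, path = NULL) {
  d <- result$decision
  ev <- result$evidence
  gene <- ev$gene
  lines <- c(
    sprintf("Locus report: %s (%s:%s-%s, %s strand)", gene$gene_id,
            gene$chrom, format(min(gene$segments$start), big.mark = ","),
            format(max(gene$segments$end), big.mark = ","), gene$strand),
    sprintf("Endpoint: %s (%s)", d$endpoint, d$endpoint_class),
    sprintf("Decision path: %s", paste(d$node_path, collapse = " -> ")),
    "Rationale:")
  for (k in names(d$rationale)) {
    lines <- c(lines, sprintf("  %-28s %s", k, d$rationale[[k]]))
  }
  same <- ev$downstream_clusters
  if (!is.null(same) && nrow(same)) {
    lines <- c(lines, sprintf("Same-strand clusters downstream: %d",
                              nrow(same)))
    for (i in seq_len(nrow(same))) {
      lines <- c(lines, sprintf(
        "  mode %s  reads %g  snr %.2f  motif %s  priming %s",
        format(same$mode[i], big.mark = ","), same$total_count[i],
        same$snr[i], same$motif_class[i], same$priming_flagged[i]))
    }
  }
  if (!is.null(d$proposal)) {
    rec <- d$proposal
    lines <- c(lines, sprintf(
      "Proposed re-annotation: %d alternative model(s), summary %s bp",
      length(rec$alternatives),
      format(rec$summary_length_bp, big.mark = ",")))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
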