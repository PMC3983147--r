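## Pipeline glue: from raw tracks to an evidence bundle and a decision.

## same-strand clusters at/downstream of the annotated 3' end, within the
## configured search window (or the 300 bp baseline-compatibility window)
.downstream_window <- function(gene, params) {
  end3 <- gene_three_prime_end(gene)
  w <- if (isTRUE(params$baseline_mode)) params$baseline_window else
    params$search_cap
  if (gene$strand == "-") c(end3 - w, end3 + params$terminus_tol) else
    c(end3 - params$terminus_tol, end3 + w)
}

#' Assemble the evidence bundle for one locus
#'
#' Runs the peak caller on the replicate 3'-end tracks, annotates clusters
#' with motif and internal-priming calls, computes bridging verdicts from
#' RNA-seq and EST coverage (EST strand ignored), junction concordance,
#' the opposite-strand stop-codon profile, and the spatial-separation
#' check, returning a [locus_evidence()] ready for [evaluate_locus()].
#'
#' @param scn a scenario (from [generate_scenario()] or [read_scenario()]),
#'   or any list with the same fields.
#' @param params a [pipeline_config()].
#' @param stranded_rnaseq whether reliable stranded RNA-seq evidence exists
#'   and supports the opposite-strand interpretation.
#' @param gene evaluate this gene model (default: the scenario's first).
#' @return a `locus_evidence`.
#' @export
assemble_locus_evidence <- function(scn, params = pipeline_config(),
                                    stranded_rnaseq = FALSE, gene = NULL) {
  if (is.null(gene)) gene <- scn$gene
  positions <- replicate_position_filter(scn$drs_tracks, params)
  clusters <- cluster_peaks(positions, params = params)
  clusters <- annotate_clusters(clusters, scn$genome, params)
  end3 <- gene_three_prime_end(gene)
  win <- .downstream_window(gene, params)
  same <- clusters[clusters$strand == gene$strand &
                     clusters$chrom == gene$chrom &
                     clusters$mode >= win[1] & clusters$mode <= win[2], ,
                   drop = FALSE]
  rownames(same) <- NULL
  opp_strand <- if (gene$strand == "-") "+" else "-"
  g_lo <- min(gene$segments$start); g_hi <- max(gene$segments$end)
  opp <- clusters[clusters$strand == opp_strand &
                    clusters$chrom == gene$chrom &
                    clusters$mode >= g_lo - 100 &
                    clusters$mode <= g_hi + 100, , drop = FALSE]
  rownames(opp) <- NULL

  region <- c(max(1, min(g_lo, win[1])),
              min(Biostrings::width(scn$genome)[1], max(g_hi, win[2])))
  vectors <- list(scn$rnaseq)
  if (!is.null(scn$est) && nrow(scn$est)) {
    vectors <- c(vectors, list(
      coverage_from_alignments(scn$est, region, chrom = gene$chrom,
                               source = "EST")))
  }
  ## does RNA-seq/EST coverage extend beyond the annotated 3' end?
  probe <- if (gene$strand == "-") {
    c(max(1, win[1]), end3 - params$terminus_tol - 1)
  } else {
    c(end3 + params$terminus_tol + 1, win[2])
  }
  evidence_extends <- probe[1] <= probe[2] && any(vapply(vectors, function(cv) {
    any(.depth_in_region(cv, probe[1], probe[2]) > 0)
  }, logical(1)))

  bridges <- lapply(seq_len(nrow(same)), function(i) {
    bridge_region(end3, same[i, ], vectors, params)
  })
  junctions <- if (!is.null(scn$junctions) && nrow(scn$junctions) ||
                   nrow(gene_introns(gene))) {
    junction_concordance(scn$junctions, gene, params$min_spanning_reads)
  } else NULL
  stop_profile <- if (nrow(opp)) {
    stop_codon_profile(scn$genome, gene$chrom, g_lo, g_hi, opp_strand)
  } else NULL
  separation <- classify_downstream_expression(gene, same, scn$rnaseq,
                                               params) ==
    "novel_feature_candidate"
  locus_evidence(gene,
                 downstream_clusters = same,
                 opposite_strand_clusters = opp,
                 bridges = bridges,
                 junctions = junctions,
                 stop_profile_opposite = stop_profile,
                 stranded_rnaseq_available = stranded_rnaseq,
                 separation_evidence = separation,
                 evidence_extends = evidence_extends)
}

#' Run the full re-annotation pipeline on a scenario
#'
#' @inheritParams assemble_locus_evidence
#' @return list of class `pipeline_result`: `positions` (retained 3'-end
#'   positions), `clusters` (annotated), `evidence`, `decision`.
#' @export
run_pipeline <- function(scn, params = pipeline_config(),
                         stranded_rnaseq = FALSE, gene = NULL) {
  evidence <- assemble_locus_evidence(scn, params, stranded_rnaseq, gene)
  decision <- evaluate_locus(evidence, params)
  positions <- replicate_position_filter(scn$drs_tracks, params)
  clusters <- annotate_clusters(cluster_peaks(positions, params = params),
                                scn$genome, params)
  structure(list(positions = positions, clusters = clusters,
                 evidence = evidence, decision = decision),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d retained position(s), %d cluster(s)\n",
              nrow(x$positions), nrow(x$clusters)))
  print(x$decision)
  invisible(x)
}
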