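## Evidence-integration decision tree. Combines peak, motif, priming,
## bridging, junction, strand and sequence evidence per locus into one of
## eight endpoints with a traced node path.
##
## Node numbering is fixed by the two canonical traversals of the manual
## curation workflow this tree encodes (1..8 for a clean extension;
## 1,2,3,9,10,11,12 / 13,14,15 for an opposite-strand locus). The remaining
## terminals (16-21) are a documented reconstruction mapping the other
## endpoint classes to the locus patterns they cover (see the vignette).
## Predicates live in one place so the mapping can be revised without
## touching callers.

.ENDPOINTS <- c(
  positive_extension            = "positive",
  positive_structure_confirmed  = "positive",
  positive_novel_model          = "positive",
  tentative_extension           = "tentative",
  tentative_opposite_strand     = "tentative",
  tentative_novel_feature       = "tentative",
  negative_insufficient         = "negative",
  negative_inconsistent         = "negative"
)

#' The decision engine's endpoint set
#' @return named character vector mapping endpoint id to its class
#'   (positive / tentative / negative).
#' @export
decision_endpoints <- function() .ENDPOINTS

#' Assemble per-locus evidence for the decision engine
#'
#' Bundles everything [evaluate_locus()] consumes. All fields are optional
#' except `gene`; missing evidence layers route the locus to
#' `negative_insufficient` with the missing layer named.
#'
#' @param gene a `gene_model`.
#' @param downstream_clusters annotated same-strand clusters (rows of an
#'   [annotate_clusters()] result) at or downstream of the gene's 3' end.
#' @param opposite_strand_clusters clusters on the opposite strand within or
#'   near the annotation.
#' @param bridges named/indexed list of `bridge_verdict`s, parallel to
#'   `downstream_clusters` rows.
#' @param junctions a `junction_support` (or `NULL` when no alignment data).
#' @param stop_profile_opposite result of [stop_codon_profile()] for the
#'   opposite-strand hypothesis region.
#' @param stranded_rnaseq_available flag: reliable stranded RNA-seq evidence
#'   exists and supports the opposite-strand interpretation.
#' @param separation_evidence flag: RNA-seq shows spatial separation between
#'   the gene end and the downstream expression block (novel-feature route).
#' @param evidence_extends flag: RNA-seq/EST coverage extends beyond the
#'   annotated 3' end.
#' @return list of class `locus_evidence`.
#' @export
locus_evidence <- function(gene, downstream_clusters = NULL,
                           opposite_strand_clusters = NULL,
                           bridges = list(), junctions = NULL,
                           stop_profile_opposite = NULL,
                           stranded_rnaseq_available = FALSE,
                           separation_evidence = FALSE,
                           evidence_extends = NA) {
  stopifnot(inherits(gene, "gene_model"))
  n_clu <- if (is.null(downstream_clusters)) 0L else nrow(downstream_clusters)
  if (length(bridges) && length(bridges) != n_clu) {
    stop("bridges must parallel downstream_clusters rows")
  }
  structure(list(gene = gene,
                 downstream_clusters = downstream_clusters,
                 opposite_strand_clusters = opposite_strand_clusters,
                 bridges = bridges, junctions = junctions,
                 stop_profile_opposite = stop_profile_opposite,
                 stranded_rnaseq_available = isTRUE(stranded_rnaseq_available),
                 separation_evidence = isTRUE(separation_evidence),
                 evidence_extends = evidence_extends),
            class = "locus_evidence")
}

#' Rank candidate poly(A) sites by motif and internal-priming evidence
#'
#' Clusters flagged as probable internal-priming artifacts are excluded
#' unless a poly(A)-signal motif supports them (a priming-flagged cluster
#' with a canonical or variant motif is retained with a warning note).
#' Accepted clusters are ranked by total read count; every accepted site is
#' a candidate alternative poly(A) site.
#'
#' @param clusters an [annotate_clusters()] result.
#' @param params a [pipeline_config()].
#' @return `clusters` with logical `accepted` and character `note` columns,
#'   accepted rows ordered first by descending total count.
#' @export
select_supported_sites <- function(clusters, params = pipeline_config()) {
  if (!nrow(clusters)) {
    clusters$accepted <- logical(0); clusters$note <- character(0)
    return(clusters)
  }
  motif_ok <- clusters$motif_class %in%
    c("canonical", "variant_ATTAAA", "variant_AATAAG", "one_mismatch",
      "tandem")
  accepted <- !clusters$priming_flagged | motif_ok
  note <- rep("", nrow(clusters))
  note[clusters$priming_flagged & motif_ok] <-
    "priming-flagged but motif-supported; retained with warning"
  note[!accepted] <- "internal-priming artifact (A-run, no motif)"
  clusters$accepted <- accepted
  clusters$note <- note
  o <- order(!clusters$accepted, -clusters$total_count)
  res <- clusters[o, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify downstream expression as UTR extension or novel feature
#'
#' When a zero-coverage separation of at least `separation_min` bp lies
#' between the annotated gene end and the block of downstream expression
#' carrying the clusters, the expression is a novel-feature candidate
#' (routed to the tentative novel-feature endpoint) rather than a 3' UTR
#' extension.
#'
#' @param gene a `gene_model`.
#' @param clusters same-strand downstream clusters.
#' @param rnaseq a `coverage_vector` spanning the downstream region.
#' @param params a [pipeline_config()].
#' @return `"utr_extension"`, `"novel_feature_candidate"`, or `"none"`.
#' @export
classify_downstream_expression <- function(gene, clusters, rnaseq,
                                           params = pipeline_config()) {
  if (is.null(clusters) || !nrow(clusters)) return("none")
  end3 <- gene_three_prime_end(gene)
  strand <- gene$strand
  distal <- if (strand == "-") min(clusters$mode) else max(clusters$mode)
  region <- sort(c(end3, distal))
  gaps <- find_gaps(rnaseq, region, min_gap_len = params$separation_min)
  if (!nrow(gaps)) return("utr_extension")
  ## a separating gap must lie between the gene end and the first covered
  ## downstream expression; a gap adjacent to the annotation end qualifies
  adjacent <- if (strand == "-") {
    any(abs(gaps$end - (end3 - 1)) <= 1)
  } else {
    any(abs(gaps$start - (end3 + 1)) <= 1)
  }
  if (adjacent) "novel_feature_candidate" else "utr_extension"
}

#' Evaluate a locus through the re-annotation decision tree
#'
#' Deterministically traverses the evidence-integration tree, records every
#' visited node, and returns an endpoint with a concrete re-annotation
#' proposal for the extension endpoints.
#'
#' @param evidence a [locus_evidence()].
#' @param params a [pipeline_config()].
#' @return list of class `reannotation_decision`: `endpoint`,
#'   `endpoint_class`, `node_path` (integer vector), `rationale` (named
#'   logical record per decision node), `chosen_clusters`, `proposal`
#'   (a `reannotation_record` or `NULL`).
#' @export
evaluate_locus <- function(evidence, params = pipeline_config()) {
  ev <- evidence
  stopifnot(inherits(ev, "locus_evidence"))
  path <- integer(0)
  rationale <- list()
  visit <- function(node) path <<- c(path, as.integer(node))
  note <- function(name, val) rationale[[name]] <<- val

  finish <- function(endpoint, chosen = NULL, proposal = NULL,
                     missing_layer = NULL) {
    structure(list(endpoint = endpoint,
                   endpoint_class = unname(.ENDPOINTS[endpoint]),
                   node_path = path, rationale = rationale,
                   chosen_clusters = chosen, proposal = proposal,
                   missing_layer = missing_layer),
              class = "reannotation_decision")
  }

  ## -- node 1: load data ---------------------------------------------------
  visit(1)
  missing <- character(0)
  if (is.null(ev$gene)) missing <- c(missing, "gene annotation")
  has_drs <- (!is.null(ev$downstream_clusters) &&
                nrow(ev$downstream_clusters) > 0) ||
    (!is.null(ev$opposite_strand_clusters) &&
       nrow(ev$opposite_strand_clusters) > 0)
  has_cov <- length(ev$bridges) > 0 || !is.null(ev$junctions) ||
    !is.na(ev$evidence_extends)
  if (!has_drs && !has_cov) missing <- c(missing, "sequencing evidence")
  note("data_loaded", length(missing) == 0)
  if (length(missing)) {
    visit(16)
    return(finish("negative_insufficient", missing_layer = missing))
  }

  ## -- node 2: existing intron/exon structure supported? -------------------
  visit(2)
  structure_ok <- is.null(ev$junctions) || ev$junctions$structure_supported
  note("structure_supported", structure_ok)
  if (!structure_ok) {
    ## node 18: does the evidence define an alternative structure instead?
    visit(18)
    alt <- !is.null(ev$junctions) && nrow(ev$junctions$novel) > 0 &&
      !is.null(ev$downstream_clusters) && nrow(ev$downstream_clusters) > 0
    note("alternative_structure", alt)
    if (alt) {
      visit(19)
      return(finish("positive_novel_model",
                    chosen = ev$downstream_clusters))
    }
    visit(16)
    return(finish("negative_insufficient",
                  missing_layer = "consistent structure evidence"))
  }

  ## -- node 3: same-strand DRS peaks downstream? ---------------------------
  visit(3)
  same <- ev$downstream_clusters
  has_same <- !is.null(same) && nrow(same) > 0
  note("downstream_peaks", has_same)

  if (has_same) {
    ## -- node 4: does RNA-seq/EST evidence extend beyond the annotation? ---
    visit(4)
    if (ev$separation_evidence) {
      note("spatially_separated", TRUE)
      visit(21)
      return(finish("tentative_novel_feature", chosen = same))
    }
    note("spatially_separated", FALSE)
    extends <- isTRUE(ev$evidence_extends)
    note("evidence_extends", extends)
    ranked <- select_supported_sites(same, params)
    accepted <- ranked[ranked$accepted, , drop = FALSE]
    if (!extends) {
      ## DRS may simply confirm the existing 3' end
      end3 <- gene_three_prime_end(ev$gene)
      confirm <- nrow(accepted) > 0 &&
        any(abs(accepted$mode - end3) <= params$terminus_tol)
      note("confirms_existing_end", confirm)
      if (confirm) {
        visit(20)
        return(finish("positive_structure_confirmed", chosen = accepted))
      }
      visit(17)
      return(finish("tentative_extension", chosen = accepted,
                    proposal = .extension_proposal(ev, accepted)))
    }

    ## -- node 5: evidence terminates near the strongest accepted cluster --
    visit(5)
    if (!nrow(accepted)) {
      note("terminates_at_strongest", FALSE)
      visit(12)
      return(finish("negative_inconsistent"))
    }
    strongest_idx <- which(same$mode == accepted$mode[1] &
                             same$total_count == accepted$total_count[1])[1]
    br <- if (length(ev$bridges) >= strongest_idx)
      ev$bridges[[strongest_idx]] else NULL
    terminates <- !is.null(br) && !is.na(br$terminus_offset) &&
      abs(br$terminus_offset) <= params$terminus_tol
    note("terminates_at_strongest", terminates)
    if (!terminates) {
      visit(17)
      return(finish("tentative_extension", chosen = accepted,
                    proposal = .extension_proposal(ev, accepted)))
    }

    ## -- node 6: continuous coverage over the proposed extension -----------
    visit(6)
    bridged <- !is.null(br) && br$status %in% c("continuous",
                                                "gapped_but_bridged")
    union_ok <- !is.null(br) && br$union_continuous
    note("continuous_coverage", union_ok)
    if (!bridged || (!is.null(br) && br$status == "unsupported")) {
      visit(16)
      return(finish("negative_insufficient",
                    missing_layer = "bridging coverage"))
    }
    if (!union_ok) {
      visit(17)
      return(finish("tentative_extension", chosen = accepted,
                    proposal = .extension_proposal(ev, accepted)))
    }

    ## -- node 7: no contradicting sequence features ------------------------
    visit(7)
    contradiction <- nrow(accepted) == 0 ||
      all(ranked$priming_flagged & !ranked$accepted)
    clean <- !contradiction
    note("no_sequence_contradiction", clean)
    if (!clean) {
      visit(12)
      return(finish("negative_inconsistent"))
    }

    ## -- node 8: positive extension ---------------------------------------
    visit(8)
    return(finish("positive_extension", chosen = accepted,
                  proposal = .extension_proposal(ev, accepted)))
  }

  ## -- node 9: opposite-strand peaks within/near the annotation? -----------
  visit(9)
  opp <- ev$opposite_strand_clusters
  has_opp <- !is.null(opp) && nrow(opp) > 0
  note("opposite_strand_peaks", has_opp)
  if (!has_opp) {
    visit(16)
    return(finish("negative_insufficient",
                  missing_layer = "3'-end peak evidence"))
  }

  ## -- node 10: is reliable stranded (non-DRS) evidence available? ---------
  ## EST strand flags are unreliable by construction, so only stranded
  ## RNA-seq counts here.
  visit(10)
  note("stranded_rnaseq_available", ev$stranded_rnaseq_available)
  if (!ev$stranded_rnaseq_available) {
    ## -- node 11: contradicting sequence features on the opposite strand --
    visit(11)
    stops_everywhere <- !is.null(ev$stop_profile_opposite) &&
      ev$stop_profile_opposite$min_across_frames > 0
    note("opposite_strand_stop_codons", stops_everywhere)
    if (stops_everywhere) {
      visit(12)
      return(finish("negative_inconsistent", chosen = opp))
    }
    visit(15)
    return(finish("tentative_opposite_strand", chosen = opp))
  }

  ## -- node 13: stranded RNA-seq confirms opposite-strand expression -------
  visit(13)
  note("stranded_rnaseq_confirms", TRUE)
  ## -- node 14: a consistent opposite-strand model can be assembled --------
  visit(14)
  consistent <- nrow(opp) > 0
  note("opposite_model_consistent", consistent)
  if (!consistent) {
    visit(12)
    return(finish("negative_inconsistent"))
  }
  visit(15)
  finish("tentative_opposite_strand", chosen = opp)
}

## Build a re-annotation proposal placing each accepted cluster mode at a
## proposed 3' UTR end (one alternative gene model per accepted site).
.extension_proposal <- function(ev, accepted) {
  if (is.null(accepted) || !nrow(accepted)) return(NULL)
  gene <- ev$gene
  end3 <- gene_three_prime_end(gene)
  strand <- gene$strand
  chrom <- gene$chrom
  seg_all <- gene$segments
  body_start <- min(seg_all$start); body_end <- max(seg_all$end)
  alts <- lapply(seq_len(nrow(accepted)), function(i) {
    m <- accepted$mode[i]
    utr <- if (strand == "-") c(m, end3 - 1) else c(end3 + 1, m)
    seg <- data.frame(
      role = c("body", "three_prime_utr"),
      chrom = chrom,
      start = c(body_start, min(utr)),
      end = c(body_end, max(utr)),
      strand = strand, stringsAsFactors = FALSE)
    gene_model(gene$gene_id, seg,
               transcript_id = paste0(gene$transcript_id, ".alt", i),
               source = "proposed")
  })
  ## summary record over the distal accepted site
  distal <- if (strand == "-") min(accepted$mode) else max(accepted$mode)
  utr <- if (strand == "-") c(distal, end3 - 1) else c(end3 + 1, distal)
  seg <- data.frame(
    role = c("body", "three_prime_utr"),
    chrom = chrom,
    start = c(body_start, min(utr)),
    end = c(body_end, max(utr)),
    strand = strand,
    evidence = c("RNA-seq/EST", "DRS/RNA-seq/EST"),
    stringsAsFactors = FALSE)
  ## body/new UTR abut by construction only when the UTR starts at end3 + 1
  rec <- tryCatch(build_reannotation_record(gene$gene_id, seg, alts),
                  error = function(e) NULL)
  rec
}

#' @export
print.reannotation_decision <- function(x, ...) {
  cat(sprintf("decision: %s (%s)\n  path: %s\n", x$endpoint,
              x$endpoint_class, paste(x$node_path, collapse = ",")))
  invisible(x)
}
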