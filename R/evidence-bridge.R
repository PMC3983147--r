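## Coverage vectors, gap finding, junction support, and bridging between an
## annotated 3' end and a candidate downstream cleavage cluster.

#' Construct a per-base coverage vector
#'
#' @param chrom contig name.
#' @param start genomic position of `depth[1]` (1-based).
#' @param depth numeric vector of read depth per base (>= 0).
#' @param source one of `"RNA-seq"`, `"EST"`, `"sRNA"`.
#' @param stranded whether the source carries reliable strand information;
#'   EST vectors are always marked strand-unreliable.
#' @param strand strand label (informational).
#' @return list of class `coverage_vector`.
#' @export
coverage_vector <- function(chrom, start, depth,
                            source = c("RNA-seq", "EST", "sRNA"),
                            stranded = FALSE, strand = "*") {
  source <- match.arg(source)
  if (any(depth < 0)) stop("coverage depths must be >= 0")
  strand_reliability <- if (source == "EST") "unreliable"
    else if (stranded) "reliable" else "none"
  structure(list(chrom = chrom, start = start, depth = as.numeric(depth),
                 source = source, stranded = stranded, strand = strand,
                 strand_reliability = strand_reliability),
            class = "coverage_vector")
}

#' @export
print.coverage_vector <- function(x, ...) {
  cat(sprintf("coverage_vector [%s] %s:%d-%d, max depth %g\n", x$source,
              x$chrom, x$start, x$start + length(x$depth) - 1, max(x$depth)))
  invisible(x)
}

## depth over an arbitrary region, zero-filled outside the stored window
.depth_in_region <- function(cv, region_start, region_end) {
  n <- region_end - region_start + 1
  out <- numeric(n)
  cv_end <- cv$start + length(cv$depth) - 1
  lo <- max(cv$start, region_start); hi <- min(cv_end, region_end)
  if (lo <= hi) {
    out[(lo - region_start + 1):(hi - region_start + 1)] <-
      cv$depth[(lo - cv$start + 1):(hi - cv$start + 1)]
  }
  out
}

#' Compute per-base coverage from alignments
#'
#' Depth is additive over reads. Gapped (spliced) alignments may be given
#' via a `blocks` list column (each element a data.frame with `start`,
#' `end`); otherwise each read covers `start..end`.
#'
#' @param alignments data.frame with `chrom, start, end` (and optionally a
#'   `blocks` list column).
#' @param region `c(start, end)` of the window to compute.
#' @param chrom contig (defaults to the first alignment's).
#' @param source passed to [coverage_vector()].
#' @return a `coverage_vector` over `region`.
#' @export
coverage_from_alignments <- function(alignments, region, chrom = NULL,
                                     source = "RNA-seq") {
  if (is.null(chrom)) chrom <- alignments$chrom[1]
  aln <- alignments[alignments$chrom == chrom, , drop = FALSE]
  if ("blocks" %in% names(aln) && nrow(aln)) {
    starts <- unlist(lapply(seq_len(nrow(aln)), function(i) {
      b <- aln$blocks[[i]]
      if (is.null(b)) aln$start[i] else b$start
    }))
    ends <- unlist(lapply(seq_len(nrow(aln)), function(i) {
      b <- aln$blocks[[i]]
      if (is.null(b)) aln$end[i] else b$end
    }))
  } else {
    starts <- aln$start; ends <- aln$end
  }
  n <- region[2] - region[1] + 1
  depth <- numeric(n)
  if (length(starts)) {
    ir <- IRanges::IRanges(pmax(starts, region[1]), pmin(ends, region[2]))
    ir <- ir[IRanges::width(ir) > 0]
    ir <- IRanges::shift(ir, 1 - region[1])
    cov <- IRanges::coverage(ir, width = n)
    depth <- as.numeric(cov)
  }
  coverage_vector(chrom, region[1], depth, source = source)
}

#' Extract splice junctions from gapped alignments
#'
#' A junction is the (donor, acceptor) pair formed by the last base of one
#' aligned block and the first base of the next, with a spanning-read count.
#'
#' @param alignments data.frame with a `blocks` list column (reads without
#'   blocks, or with a single block, contribute no junctions).
#' @param chrom restrict to one contig when given.
#' @return data.frame `chrom, donor, acceptor, count`.
#' @export
junctions_from_alignments <- function(alignments, chrom = NULL) {
  out <- data.frame(chrom = character(0), donor = numeric(0),
                    acceptor = numeric(0), count = integer(0))
  if (!"blocks" %in% names(alignments)) return(out)
  recs <- list()
  for (i in seq_len(nrow(alignments))) {
    b <- alignments$blocks[[i]]
    if (is.null(b) || nrow(b) < 2) next
    b <- b[order(b$start), , drop = FALSE]
    for (j in seq_len(nrow(b) - 1)) {
      recs[[length(recs) + 1]] <- data.frame(
        chrom = alignments$chrom[i], donor = b$end[j],
        acceptor = b$start[j + 1], stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(out)
  jx <- do.call(rbind, recs)
  if (!is.null(chrom)) jx <- jx[jx$chrom == chrom, , drop = FALSE]
  agg <- stats::aggregate(list(count = rep(1L, nrow(jx))),
                          by = jx[c("chrom", "donor", "acceptor")], FUN = sum)
  agg[order(agg$chrom, agg$donor), , drop = FALSE]
}

#' Find zero-depth gaps in a coverage vector
#'
#' Maximal runs of zero depth of at least `min_gap_len` bases within
#' `region`, reported with genomic coordinates.
#'
#' @param cv a `coverage_vector`.
#' @param region `c(start, end)`; defaults to the vector's extent.
#' @param min_gap_len minimum run length in bp.
#' @return data.frame `start, end, length` (length = number of zero bases).
#' @export
find_gaps <- function(cv, region = NULL, min_gap_len = 50L) {
  if (is.null(region)) region <- c(cv$start, cv$start + length(cv$depth) - 1)
  d <- .depth_in_region(cv, region[1], region[2])
  r <- rle(d == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_gap_len
  data.frame(start = region[1] + starts[keep] - 1,
             end = region[1] + ends[keep] - 1,
             length = r$lengths[keep])
}

## pointwise union (max) of several coverage vectors over a region
.union_depth <- function(vectors, region) {
  mats <- vapply(vectors, .depth_in_region, numeric(region[2] - region[1] + 1),
                 region_start = region[1], region_end = region[2])
  if (is.null(dim(mats))) mats <- matrix(mats, ncol = length(vectors))
  apply(mats, 1, max)
}

#' Bridge an annotated 3' end to a candidate downstream cleavage cluster
#'
#' Quantifies whether transcription evidence (RNA-seq, EST, ...) connects
#' the annotated gene end to the cluster. Per-source zero-coverage gaps of
#' at least `min_gap_len` bp are located, each checked for coverage by the
#' union of the other sources; EST strandedness is ignored for bridging
#' (archival EST strand flags are unreliable).
#'
#' Verdicts: `continuous` when at least one source alone covers the
#' extension without a significant gap; `gapped_but_bridged` when no single
#' source does but the union of sources has no significant gap, or when
#' union gaps remain but all are shorter than `unbridged_max` with at least
#' `min_covered_frac` of the extension covered; `unsupported` otherwise.
#'
#' @param annotation_end genomic position of the currently annotated 3' end.
#' @param cluster one row of a [cluster_peaks()] result (or a list with
#'   `mode` and `strand`).
#' @param vectors list of `coverage_vector`s.
#' @param params a [pipeline_config()].
#' @return list of class `bridge_verdict`: `status`, `gaps` (data.frame
#'   with `source, start, end, length, covered_by_other_source`),
#'   `union_gaps`, `union_continuous`, `terminus_offset` (cluster mode minus
#'   furthest covered base, transcription sense; negative when evidence
#'   runs past the cluster), `covered_frac`.
#' @export
bridge_region <- function(annotation_end, cluster, vectors,
                          params = pipeline_config()) {
  strand <- cluster$strand
  mode_pos <- cluster$mode
  ## clusters slightly upstream (within the terminus tolerance, i.e.
  ## confirming the existing end) are allowed; anything further is an error
  tol <- params$terminus_tol
  if ((strand != "-" && mode_pos < annotation_end - tol) ||
      (strand == "-" && mode_pos > annotation_end + tol)) {
    stop("ordering error: cluster is upstream of the annotation end")
  }
  region <- sort(c(annotation_end, mode_pos))
  min_gap <- params$min_gap_len
  per_source <- lapply(vectors, find_gaps, region = region,
                       min_gap_len = min_gap)
  src_names <- vapply(vectors, `[[`, "", "source")
  gaps <- list()
  for (i in seq_along(vectors)) {
    g <- per_source[[i]]
    if (!nrow(g)) next
    others <- vectors[-i]
    g$covered_by_other_source <- vapply(seq_len(nrow(g)), function(j) {
      if (!length(others)) return(FALSE)
      ud <- .union_depth(others, c(g$start[j], g$end[j]))
      all(ud > 0)
    }, logical(1))
    g$source <- src_names[i]
    gaps[[length(gaps) + 1]] <- g
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(start = numeric(0), end = numeric(0), length = numeric(0),
               covered_by_other_source = logical(0), source = character(0))
  ud <- .union_depth(vectors, region)
  union_cv <- coverage_vector(cluster$chrom %||% vectors[[1]]$chrom,
                              region[1], ud, source = "RNA-seq")
  union_gaps <- find_gaps(union_cv, region, min_gap)
  union_continuous <- nrow(union_gaps) == 0
  covered_frac <- mean(ud > 0)
  any_source_continuous <- any(vapply(per_source, nrow, 0L) == 0L)
  status <- if (union_continuous && any_source_continuous) {
    "continuous"
  } else if (union_continuous) {
    "gapped_but_bridged"
  } else if (max(union_gaps$length) < params$unbridged_max &&
             covered_frac >= params$min_covered_frac) {
    "gapped_but_bridged"
  } else {
    "unsupported"
  }
  ## furthest covered base in transcription direction, over the full extent
  ## of the supplied vectors (evidence may run past the cluster mode)
  cov_end <- NA_real_
  for (cv in vectors) {
    covered <- which(cv$depth > 0)
    if (!length(covered)) next
    pos <- cv$start + covered - 1
    cand <- if (strand == "-") min(pos) else max(pos)
    cov_end <- if (is.na(cov_end)) cand else
      if (strand == "-") min(cov_end, cand) else max(cov_end, cand)
  }
  terminus_offset <- if (is.na(cov_end)) NA_real_ else
    if (strand == "-") cov_end - mode_pos else mode_pos - cov_end
  structure(list(status = status, gaps = gaps, union_gaps = union_gaps,
                 union_continuous = union_continuous,
                 terminus_offset = terminus_offset,
                 covered_frac = covered_frac),
            class = "bridge_verdict")
}

#' Junction support for a gene model's annotated introns
#'
#' Each annotated intron is labelled `supported` when at least
#' `min_spanning_reads` reads span its exact boundaries, `weak` for 1 to
#' threshold-1 reads, and `unsupported` for none. Observed junctions that
#' match no annotated intron are reported as novel.
#'
#' @param junctions data.frame from [junctions_from_alignments()].
#' @param gene a `gene_model`.
#' @param min_spanning_reads threshold for `supported`.
#' @return list of class `junction_support`: `introns` (data.frame with
#'   `start, end, spanning_reads, verdict`), `novel` (unmatched observed
#'   junctions), `structure_supported` (no intron is `unsupported`).
#' @export
junction_concordance <- function(junctions, gene, min_spanning_reads = 3L) {
  intr <- gene_introns(gene)
  res <- data.frame(start = intr$start, end = intr$end,
                    spanning_reads = 0L, verdict = "unsupported",
                    stringsAsFactors = FALSE)
  jx <- junctions
  if (!is.null(jx) && nrow(jx)) jx <- jx[jx$chrom == gene$chrom, , drop = FALSE]
  matched <- logical(if (is.null(jx)) 0 else nrow(jx))
  if (nrow(res) && !is.null(jx) && nrow(jx)) {
    for (i in seq_len(nrow(res))) {
      hit <- jx$donor == res$start[i] - 1 & jx$acceptor == res$end[i] + 1
      if (any(hit)) {
        res$spanning_reads[i] <- sum(jx$count[hit])
        matched[hit] <- TRUE
      }
    }
    res$verdict <- ifelse(res$spanning_reads >= min_spanning_reads, "supported",
                          ifelse(res$spanning_reads >= 1, "weak", "unsupported"))
  }
  novel <- if (!is.null(jx) && nrow(jx)) jx[!matched, , drop = FALSE] else
    data.frame(chrom = character(0), donor = numeric(0),
               acceptor = numeric(0), count = integer(0))
  structure(list(introns = res, novel = novel,
                 structure_supported = !any(res$verdict == "unsupported")),
            class = "junction_support")
}
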