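## Small-RNA integration: mature miRNA 5p/3p arm pairs, pri-miRNA
## delineation, and un-paired short-feature candidates (snoRNA-like).

#' Find peaks in a small-RNA coverage vector
#'
#' A peak is a maximal run of depth at or above `min_height`, summarized by
#' its footprint and maximum depth. sRNA reads are treated as un-stranded.
#'
#' @param srna a `coverage_vector` (source `"sRNA"`).
#' @param min_height absolute depth threshold; when `NULL`, the
#'   `srna_peak_percentile` quantile of the positive depths is used.
#' @param params a [pipeline_config()].
#' @return data.frame `start, end, width, height`.
#' @export
find_srna_peaks <- function(srna, min_height = NULL,
                            params = pipeline_config()) {
  d <- srna$depth
  if (is.null(min_height)) {
    pos <- d[d > 0]
    min_height <- if (length(pos)) {
      stats::quantile(pos, params$srna_peak_percentile, names = FALSE)
    } else Inf
  }
  r <- rle(d >= min_height & d > 0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values
  out <- data.frame(start = srna$start + starts[keep] - 1,
                    end = srna$start + ends[keep] - 1)
  out$width <- out$end - out$start + 1
  out$height <- vapply(seq_len(nrow(out)), function(i) {
    max(d[(out$start[i] - srna$start + 1):(out$end[i] - srna$start + 1)])
  }, numeric(1))
  out
}

#' Detect mature miRNA 5p/3p arm pairs
#'
#' Pairs of short sRNA peaks (footprint within `arm_footprint` bounds)
#' separated by a hairpin-loop-scale gap (`arm_gap` bounds) are arm pairs.
#' The dominant arm is the higher peak, unless the heights are within the
#' `arm_dominance_ratio` tolerance, in which case the pair is `balanced`.
#' The 5p arm is the transcriptionally upstream peak.
#'
#' @param srna a `coverage_vector`.
#' @param strand transcription strand of the locus (inherited from DRS
#'   evidence; sRNA reads themselves are un-stranded).
#' @param min_height passed to [find_srna_peaks()].
#' @param params a [pipeline_config()].
#' @return data.frame of class `arm_pairs`: one row per pair with
#'   `five_p_start, five_p_end, five_p_height, three_p_start, three_p_end,
#'   three_p_height, inter_peak_gap, dominant_arm`.
#' @export
detect_arm_pairs <- function(srna, strand = "+", min_height = NULL,
                             params = pipeline_config()) {
  peaks <- find_srna_peaks(srna, min_height, params)
  fp <- params$arm_footprint; gp <- params$arm_gap
  arms <- peaks[peaks$width >= fp[1] & peaks$width <= fp[2], , drop = FALSE]
  empty <- data.frame(five_p_start = numeric(0), five_p_end = numeric(0),
                      five_p_height = numeric(0), three_p_start = numeric(0),
                      three_p_end = numeric(0), three_p_height = numeric(0),
                      inter_peak_gap = numeric(0),
                      dominant_arm = character(0))
  class(empty) <- c("arm_pairs", class(empty))
  if (nrow(arms) < 2) return(empty)
  arms <- arms[order(arms$start), , drop = FALSE]
  pairs <- list()
  i <- 1
  while (i < nrow(arms)) {
    gap <- arms$start[i + 1] - arms$end[i] - 1
    if (gap >= gp[1] && gap <= gp[2]) {
      left <- arms[i, ]; right <- arms[i + 1, ]
      if (strand == "-") { five <- right; three <- left } else {
        five <- left; three <- right
      }
      ratio <- max(five$height, three$height) /
        max(min(five$height, three$height), 1e-9)
      dominant <- if (ratio <= params$arm_dominance_ratio) "balanced"
        else if (five$height > three$height) "5p" else "3p"
      pairs[[length(pairs) + 1]] <- data.frame(
        five_p_start = five$start, five_p_end = five$end,
        five_p_height = five$height,
        three_p_start = three$start, three_p_end = three$end,
        three_p_height = three$height,
        inter_peak_gap = gap, dominant_arm = dominant,
        stringsAsFactors = FALSE)
      i <- i + 2
    } else {
      i <- i + 1
    }
  }
  if (!length(pairs)) return(empty)
  res <- do.call(rbind, pairs)
  class(res) <- c("arm_pairs", class(res))
  res
}

#' Delineate a pri-miRNA transcript from flanking RNA-seq blocks
#'
#' The polyadenylated primary transcript is modeled as the RNA-seq covered
#' blocks flanking zero-coverage hairpin-excision zones (the pre-miRNA is
#' cut out co-transcriptionally, so no long-RNA reads remain over the
#' arms), with its 3' end at the DRS cleavage cluster downstream of the
#' 3'-most arm.
#'
#' @param rnaseq a `coverage_vector` over the locus.
#' @param clusters DRS clusters (same strand as the locus).
#' @param arm_pairs an [detect_arm_pairs()] result (must be non-empty).
#' @param strand locus strand.
#' @param max_cluster_distance how far downstream of the 3'-most arm the
#'   terminal cluster may lie (bp).
#' @param params a [pipeline_config()].
#' @return list of class `pri_mirna`: `extent` (`genome_interval`),
#'   `three_prime_end` (cluster mode or `NA`), `status` (`"anchored"` or
#'   `"open_ended"`), `excision_gaps` (data.frame), `arm_pairs`; or `NULL`
#'   when no arm pairs are supplied.
#' @export
delineate_pri_mirna <- function(rnaseq, clusters, arm_pairs, strand = "+",
                                max_cluster_distance = 500L,
                                params = pipeline_config()) {
  if (is.null(arm_pairs) || !nrow(arm_pairs)) return(NULL)
  arm_lo <- min(arm_pairs$five_p_start, arm_pairs$three_p_start)
  arm_hi <- max(arm_pairs$five_p_end, arm_pairs$three_p_end)
  ## zero-coverage excision zones overlapping the arms
  gaps <- find_gaps(rnaseq, min_gap_len = 10L)
  excision <- gaps[gaps$end >= arm_lo & gaps$start <= arm_hi, , drop = FALSE]
  ## 3' end: nearest accepted cluster downstream of the 3'-most arm
  three_end <- NA_real_
  if (!is.null(clusters) && nrow(clusters)) {
    cand <- if (strand == "-") {
      clusters[clusters$mode <= arm_lo &
                 clusters$mode >= arm_lo - max_cluster_distance, , drop = FALSE]
    } else {
      clusters[clusters$mode >= arm_hi &
                 clusters$mode <= arm_hi + max_cluster_distance, , drop = FALSE]
    }
    if (nrow(cand)) {
      three_end <- if (strand == "-") max(cand$mode) else min(cand$mode)
    }
  }
  covered <- which(rnaseq$depth > 0)
  cov_lo <- rnaseq$start + min(covered) - 1
  cov_hi <- rnaseq$start + max(covered) - 1
  lo <- min(cov_lo, arm_lo); hi <- max(cov_hi, arm_hi)
  if (!is.na(three_end)) {
    if (strand == "-") lo <- three_end else hi <- three_end
  }
  extent <- genome_interval(rnaseq$chrom, lo, hi, strand)
  structure(list(extent = extent, three_prime_end = three_end,
                 status = if (is.na(three_end)) "open_ended" else "anchored",
                 excision_gaps = excision, arm_pairs = arm_pairs),
            class = "pri_mirna")
}

#' Call an un-paired short-feature candidate (snoRNA-like)
#'
#' Emitted when a single sRNA peak lacking the two-peak mature-miRNA
#' structure coincides with a low-level RNA-seq expression block and
#' multiple weak DRS clusters. Mutually exclusive with arm-pair detection
#' on the same peak set: when arm pairs are present the locus is routed to
#' the miRNA logic instead.
#'
#' @param srna a `coverage_vector`.
#' @param clusters DRS clusters over the scanned region.
#' @param rnaseq a `coverage_vector` over the scanned region.
#' @param strand strand inherited from the DRS clusters.
#' @param external_prediction optional flag/interval from an external
#'   short-RNA prediction (e.g. a snoRNA predictor) supplied as input.
#' @param min_height passed to [find_srna_peaks()].
#' @param params a [pipeline_config()].
#' @return list of class `short_feature_candidate` (fields `interval`,
#'   `srna_peak_height`, `drs_cluster_count`, `rnaseq_block`,
#'   `has_two_peak_structure`, `external_prediction`), or `NULL` when the
#'   evidence does not support a candidate.
#' @export
call_short_feature <- function(srna, clusters, rnaseq, strand = "+",
                               external_prediction = NULL, min_height = NULL,
                               params = pipeline_config()) {
  pairs <- detect_arm_pairs(srna, strand, min_height, params)
  if (nrow(pairs)) return(NULL)   # miRNA logic owns paired peaks
  peaks <- find_srna_peaks(srna, min_height, params)
  if (!nrow(peaks)) return(NULL)
  top <- peaks[which.max(peaks$height), ]
  ## coincident RNA-seq expression block
  r <- rle(rnaseq$depth > 0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  blk <- data.frame(start = rnaseq$start + starts[r$values] - 1,
                    end = rnaseq$start + ends[r$values] - 1)
  hit <- blk[blk$start <= top$end & blk$end >= top$start, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  block <- hit[1, ]
  n_clu <- if (is.null(clusters) || !nrow(clusters)) 0L else {
    sum(clusters$mode >= block$start - 100 & clusters$mode <= block$end + 100)
  }
  if (n_clu < 2L) return(NULL)
  structure(list(
    interval = genome_interval(srna$chrom, top$start, top$end, strand),
    srna_peak_height = top$height,
    drs_cluster_count = n_clu,
    rnaseq_block = genome_interval(rnaseq$chrom, block$start, block$end,
                                   strand),
    has_two_peak_structure = FALSE,
    external_prediction = external_prediction),
    class = "short_feature_candidate")
}
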