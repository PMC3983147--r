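## Strand-specific 3'-end read filtering, per-position counting, replicate
## concordance with Poisson signal-to-noise, and single-linkage peak
## clustering.

.count_cigar_indels <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    if (is.na(cigar[i])) return(NA_integer_)
    toks <- regmatches(cigar[i], ops[i])[[1]]
    kinds <- substring(toks, nchar(toks))
    lens <- as.integer(substring(toks, 1, nchar(toks) - 1))
    sum(lens[kinds %in% c("I", "D")])
  }, integer(1))
}

.cigar_read_length <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    if (is.na(cigar[i])) return(NA_integer_)
    toks <- regmatches(cigar[i], ops[i])[[1]]
    kinds <- substring(toks, nchar(toks))
    lens <- as.integer(substring(toks, 1, nchar(toks) - 1))
    sum(lens[kinds %in% c("M", "I", "S", "=", "X")])
  }, integer(1))
}

#' Filter 3'-end sequencing alignments
#'
#' Retains exactly the reads with unique, high-quality mappings, at most
#' `max_indels` indels ("fewer than four" under the default of 3) and read
#' length of at least `min_read_length` bases. Uniqueness is taken from a
#' logical `unique` column when present; otherwise a record is unique when
#' it is not flagged secondary/supplementary and its mapping quality is at
#' least `min_mapq`.
#'
#' @param alignments a data.frame with columns `chrom`, `start`, `end`,
#'   `strand` plus either (`n_indels`, `read_length`) or a `cigar` column
#'   from which both are derived, and uniqueness information (`unique`, or
#'   `mapq`/`secondary`). Records with an unparseable/missing cigar and no
#'   explicit counts are dropped with a warning.
#' @param params a [pipeline_config()].
#' @return list with `alignments` (the retained rows) and `stats` (counts
#'   removed per criterion).
#' @export
filter_reads <- function(alignments, params = pipeline_config()) {
  aln <- alignments
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(aln))) {
    stop("alignments need columns: ", paste(need, collapse = ", "))
  }
  n_in <- nrow(aln)
  dropped_nocigar <- 0L
  if (!all(c("n_indels", "read_length") %in% names(aln))) {
    if (!"cigar" %in% names(aln)) {
      stop("alignments need n_indels+read_length columns or a cigar column")
    }
    bad <- is.na(aln$cigar) | !nzchar(aln$cigar)
    if (any(bad)) {
      warning(sum(bad), " alignment(s) lack a cigar and were dropped")
      dropped_nocigar <- sum(bad)
      aln <- aln[!bad, , drop = FALSE]
    }
    aln$n_indels <- .count_cigar_indels(aln$cigar)
    aln$read_length <- .cigar_read_length(aln$cigar)
  }
  uniq <- if ("unique" %in% names(aln)) {
    as.logical(aln$unique)
  } else {
    sec <- if ("secondary" %in% names(aln)) as.logical(aln$secondary) else FALSE
    mq <- if ("mapq" %in% names(aln)) aln$mapq else Inf
    !sec & mq >= params$min_mapq
  }
  keep_unique <- if (params$require_unique) uniq else rep(TRUE, nrow(aln))
  keep_indels <- aln$n_indels <= params$max_indels
  keep_len <- aln$read_length >= params$min_read_length
  keep <- keep_unique & keep_indels & keep_len
  stats <- list(
    input = n_in,
    retained = sum(keep),
    removed_no_cigar = dropped_nocigar,
    removed_nonunique = sum(!keep_unique),
    removed_indels = sum(keep_unique & !keep_indels),
    removed_short = sum(keep_unique & keep_indels & !keep_len)
  )
  list(alignments = aln[keep, , drop = FALSE], stats = stats)
}

#' Count aligned 3' ends per genomic position
#'
#' Each plus-strand read contributes one count at its highest aligned
#' coordinate, each minus-strand read at its lowest: the 3'-terminal aligned
#' base in transcription sense. Total counts are conserved (one per read).
#'
#' @param alignments filtered alignment data.frame (`chrom,start,end,strand`).
#' @param replicate_id identifier stored on the track.
#' @return A `three_prime_track`: data.frame `chrom, pos, strand, count`
#'   with attribute `replicate_id`.
#' @export
count_three_prime_ends <- function(alignments, replicate_id = "rep1") {
  aln <- alignments
  stopifnot(all(aln$strand %in% c("+", "-")))
  pos <- ifelse(aln$strand == "+", aln$end, aln$start)
  key <- paste(aln$chrom, pos, aln$strand)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(agg$key, " ", fixed = TRUE))
  tr <- data.frame(chrom = parts[, 1], pos = as.numeric(parts[, 2]),
                   strand = parts[, 3], count = agg$Freq,
                   stringsAsFactors = FALSE)
  tr <- tr[order(tr$chrom, tr$strand, tr$pos), , drop = FALSE]
  rownames(tr) <- NULL
  three_prime_track(tr, replicate_id)
}

#' Construct/validate a per-replicate 3'-end count track
#' @param df data.frame with columns `chrom, pos, strand, count`.
#' @param replicate_id replicate label.
#' @return the validated data.frame, classed `three_prime_track`.
#' @export
three_prime_track <- function(df, replicate_id = "rep1") {
  stopifnot(all(c("chrom", "pos", "strand", "count") %in% names(df)),
            all(df$count >= 1), all(df$strand %in% c("+", "-")))
  attr(df, "replicate_id") <- replicate_id
  class(df) <- c("three_prime_track", class(df))
  df
}

#' Replicate-concordance position filter with Poisson signal-to-noise
#'
#' A position is retained when its 3'-end count reaches
#' `min_reads_per_replicate` in every required replicate (default: all of
#' them), and its total Poisson signal-to-noise ratio
#' `snr = total / sqrt(total)` reaches `snr_min`. At the default thresholds
#' (3 reads in each of 3 replicates) the minimum retained evidence is 9
#' reads with snr exactly 3. In `singleton_mode` (single-replicate
#' datasets) only singleton positions (count 1) are dropped and no
#' signal-to-noise floor is applied.
#'
#' @param tracks list of `three_prime_track` objects (one per replicate).
#' @param params a [pipeline_config()].
#' @return data.frame `chrom, pos, strand`, one count column per replicate,
#'   `total`, `snr`.
#' @export
replicate_position_filter <- function(tracks, params = pipeline_config()) {
  if (inherits(tracks, "three_prime_track")) tracks <- list(tracks)
  if (!length(tracks)) stop("configuration error: zero replicate tracks")
  k <- length(tracks)
  rep_ids <- vapply(seq_len(k), function(i) {
    id <- attr(tracks[[i]], "replicate_id")
    if (is.null(id)) paste0("rep", i) else as.character(id)
  }, "")
  keys <- lapply(tracks, function(tr) paste(tr$chrom, tr$pos, tr$strand))
  all_keys <- unique(unlist(keys))
  mat <- matrix(0, nrow = length(all_keys), ncol = k,
                dimnames = list(all_keys, rep_ids))
  for (i in seq_len(k)) {
    mat[keys[[i]], i] <- tracks[[i]]$count
  }
  total <- rowSums(mat)
  if (isTRUE(params$singleton_mode)) {
    if (k != 1L) stop("singleton_mode applies to single-replicate data")
    keep <- total >= 2
  } else {
    min_reps <- params$min_replicates
    if (is.na(min_reps)) min_reps <- k
    n_ok <- rowSums(mat >= params$min_reads_per_replicate)
    keep <- n_ok >= min_reps
    if (!is.null(params$snr_min) && !is.na(params$snr_min)) {
      keep <- keep & sqrt(total) >= params$snr_min
    }
  }
  if (!any(keep)) {
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      strand = character(0))
    for (id in rep_ids) out[[id]] <- numeric(0)
    out$total <- numeric(0); out$snr <- numeric(0)
    return(out)
  }
  parts <- do.call(rbind, strsplit(all_keys[keep], " ", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], pos = as.numeric(parts[, 2]),
                    strand = parts[, 3], stringsAsFactors = FALSE)
  cnt <- mat[keep, , drop = FALSE]
  for (i in seq_len(k)) out[[rep_ids[i]]] <- unname(cnt[, i])
  out$total <- unname(total[keep])
  out$snr <- out$total / sqrt(out$total)
  out <- out[order(out$chrom, out$strand, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-linkage clustering of retained cleavage positions
#'
#' Consecutive positions no more than `max_cluster_gap` bp apart (per
#' chromosome and strand) join one poly(A) peak cluster. The cluster mode is
#' the highest-count member position, ties broken towards the most 3'
#' position in transcription direction (the distal cleavage site). The
#' subpeak count is the number of local count maxima across member
#' positions (a flat plateau counts once).
#'
#' @param positions output of [replicate_position_filter()] (needs columns
#'   `chrom, pos, strand, total`; replicate columns are carried through).
#' @param max_cluster_gap bp; default from `params`.
#' @param params a [pipeline_config()].
#' @return data.frame of clusters: `chrom, start, end, strand, mode,
#'   total_count, snr, n_positions, subpeak_count` plus a `members` list
#'   column of per-position data.
#' @export
cluster_peaks <- function(positions, max_cluster_gap = NULL,
                          params = pipeline_config()) {
  if (is.null(max_cluster_gap)) max_cluster_gap <- params$max_cluster_gap
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      mode = numeric(0), total_count = numeric(0),
                      snr = numeric(0), n_positions = integer(0),
                      subpeak_count = integer(0))
  empty$members <- list()
  if (!nrow(positions)) return(empty)
  grp <- paste(positions$chrom, positions$strand)
  out <- list()
  for (g in unique(grp)) {
    sub <- positions[grp == g, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    breaks <- c(0, cumsum(diff(sub$pos) > max_cluster_gap))
    for (b in unique(breaks)) {
      mem <- sub[breaks == b, , drop = FALSE]
      tot <- sum(mem$total)
      cnt <- mem$total
      ## mode: max count, tie towards transcriptionally 3'-most position
      best <- which(cnt == max(cnt))
      mode_pos <- if (mem$strand[1] == "-") min(mem$pos[best]) else
        max(mem$pos[best])
      ## local maxima at base resolution: positions separated by uncovered
      ## bases are distinct subpeaks, a flat plateau counts once
      profile <- numeric(max(mem$pos) - min(mem$pos) + 1)
      profile[mem$pos - min(mem$pos) + 1] <- cnt
      r <- rle(profile)$values
      n_sub <- if (length(r) == 1L) 1L else {
        sum(vapply(seq_along(r), function(i) {
          left <- if (i == 1L) -Inf else r[i - 1]
          right <- if (i == length(r)) -Inf else r[i + 1]
          r[i] > left && r[i] > right
        }, logical(1)))
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = mem$chrom[1], start = min(mem$pos), end = max(mem$pos),
        strand = mem$strand[1], mode = mode_pos, total_count = tot,
        snr = tot / sqrt(tot), n_positions = nrow(mem),
        subpeak_count = as.integer(n_sub), stringsAsFactors = FALSE)
      out[[length(out)]]$members <- list(mem)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$strand, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("polya_clusters", class(res))
  res
}

#' Annotate clusters with poly(A)-signal and internal-priming calls
#'
#' Convenience wrapper running [scan_pas_motif()] and
#' [assess_internal_priming()] at every cluster mode against a genome.
#'
#' @param clusters output of [cluster_peaks()].
#' @param genome a named `DNAStringSet` (or object coercible by
#'   `Biostrings::DNAStringSet`).
#' @param params a [pipeline_config()].
#' @return `clusters` with added columns `motif_class`, `motif_seq`,
#'   `motif_distance`, `motif_mismatches`, `priming_flagged`, `max_a_run`.
#' @export
annotate_clusters <- function(clusters, genome, params = pipeline_config()) {
  if (!nrow(clusters)) {
    clusters$motif_class <- character(0)
    clusters$motif_seq <- character(0)
    clusters$motif_distance <- numeric(0)
    clusters$motif_mismatches <- numeric(0)
    clusters$priming_flagged <- logical(0)
    clusters$max_a_run <- integer(0)
    return(clusters)
  }
  hits <- lapply(seq_len(nrow(clusters)), function(i) {
    scan_pas_motif(genome, clusters$chrom[i], clusters$mode[i],
                   clusters$strand[i], window = params$pas_window,
                   params = params)
  })
  prim <- lapply(seq_len(nrow(clusters)), function(i) {
    assess_internal_priming(genome, clusters$chrom[i], clusters$mode[i],
                            clusters$strand[i],
                            window_down = params$priming_window_down,
                            min_a_run = params$priming_min_a_run,
                            a_fraction = params$priming_a_fraction)
  })
  clusters$motif_class <- vapply(hits, `[[`, "", "motif_class")
  clusters$motif_seq <- vapply(hits, `[[`, "", "matched_sequence")
  clusters$motif_distance <- vapply(hits, `[[`, 0, "distance_upstream")
  clusters$motif_mismatches <- vapply(hits, `[[`, 0, "mismatches")
  clusters$priming_flagged <- vapply(prim, `[[`, TRUE, "flagged")
  clusters$max_a_run <- vapply(prim, function(p) as.integer(p$max_a_run),
                               integer(1))
  clusters
}

#' Write clusters as BED6 (score = total count, thickStart = mode) and TSV
#'
#' @param clusters output of [cluster_peaks()].
#' @param bed_path,tsv_path output files (either may be `NULL`).
#' @return invisible list of written paths.
#' @export
write_clusters <- function(clusters, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    lines <- character(0)
    for (i in seq_len(nrow(clusters))) {
      bc <- to_bed_coords(clusters$start[i], clusters$end[i])
      mc <- to_bed_coords(clusters$mode[i], clusters$mode[i])
      lines <- c(lines, paste(clusters$chrom[i], bc$start, bc$end,
                              sprintf("cluster_%03d", i),
                              clusters$total_count[i], clusters$strand[i],
                              mc$start, mc$end, sep = "\t"))
    }
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path)) {
    flat <- clusters[, setdiff(names(clusters), "members"), drop = FALSE]
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}
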