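## Genomic-sequence checks at candidate cleavage sites: poly(A)-signal
## hexamers, internal-priming adenosine runs, stop-codon density, AT content.

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (inherits(genome, "DNAString")) {
    gs <- Biostrings::DNAStringSet(genome)
    names(gs) <- "seq"
    return(gs)
  }
  if (is.character(genome)) {
    gs <- Biostrings::DNAStringSet(genome)
    if (is.null(names(gs))) names(gs) <- paste0("seq", seq_along(gs))
    return(gs)
  }
  stop("genome must be a DNAStringSet, DNAString or character vector")
}

## Extract sequence in transcription sense. Truncates at contig bounds with
## a warning; returns the string plus how many bases were clipped 5'-side.
.sense_seq <- function(genome, chrom, from, to, strand) {
  genome <- .as_genome(genome)
  if (!chrom %in% names(genome)) stop("unknown contig: ", chrom)
  len <- Biostrings::width(genome[chrom])
  cf <- max(1, from); ct <- min(len, to)
  if (cf > from || ct < to) {
    warning("scan window truncated at contig bounds (", chrom, ")")
  }
  if (cf > ct) return(list(seq = "", clip5 = 0L))
  s <- as.character(Biostrings::subseq(genome[[chrom]], cf, ct))
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    clip5 <- to - ct     # bases lost at the transcription-sense 5' side
  } else {
    clip5 <- cf - from
  }
  list(seq = s, clip5 = as.integer(clip5))
}

.hamming6 <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Scan for a poly(A)-signal motif upstream of a cleavage site
#'
#' Searches the transcription-sense sequence upstream of `cleavage_pos` for
#' the canonical AATAAA hexamer allowing at most one mismatch, the exact
#' named variants ATTAAA and AATAAG, and the tandem 10-mer AATAAATAAA. The
#' distance is measured from the motif's 3'-most base to the cleavage
#' position (transcription-strand sense); only motifs whose distance falls
#' inside `window` are considered. The best hit has the fewest mismatches,
#' ties broken by distance closest to the modal observed offset (19 bp).
#' Hexamers overlapping an ambiguous base (N) never match.
#'
#' @param genome named `DNAStringSet` (or character/`DNAString`).
#' @param chrom contig name.
#' @param cleavage_pos 1-based position of the cleavage site.
#' @param strand `"+"` or `"-"`.
#' @param window `c(min_up, max_up)` distance bounds in bp.
#' @param params a [pipeline_config()] (supplies `pas_modal_distance`).
#' @return list of class `pas_motif_hit`: `motif_class` (one of
#'   `"canonical"`, `"variant_ATTAAA"`, `"variant_AATAAG"`,
#'   `"one_mismatch"`, `"tandem"`, `"none"`), `matched_sequence`,
#'   `distance_upstream`, `mismatches`.
#' @export
scan_pas_motif <- function(genome, chrom, cleavage_pos, strand = "+",
                           window = c(10L, 40L), params = pipeline_config()) {
  min_up <- as.integer(window[1]); max_up <- as.integer(window[2])
  stopifnot(min_up >= 1, max_up >= min_up)
  L <- max_up + 5L
  ss <- if (strand == "-") {
    .sense_seq(genome, chrom, cleavage_pos + min_up,
               cleavage_pos + max_up + 5L, strand)
  } else {
    .sense_seq(genome, chrom, cleavage_pos - max_up - 5L,
               cleavage_pos - min_up, strand)
  }
  up <- ss$seq
  none <- structure(list(motif_class = "none", matched_sequence = NA_character_,
                         distance_upstream = NA_real_, mismatches = NA_real_),
                    class = "pas_motif_hit")
  if (!nzchar(up)) return(none)
  chars <- strsplit(up, "")[[1]]
  n <- length(chars)
  offset <- ss$clip5   # up[1] corresponds to full-window index offset+1
  canonical <- strsplit("AATAAA", "")[[1]]
  hits <- list()
  for (i in seq_len(max(0, n - 5L))) {
    hex <- chars[i:(i + 5L)]
    if (any(!hex %in% c("A", "C", "G", "T"))) next
    d <- max_up + 1L - (i + offset)   # distance of motif 3' end to cleavage
    if (d < min_up || d > max_up) next
    mm <- sum(hex != canonical)
    hs <- paste(hex, collapse = "")
    cls <- if (mm == 0L) "canonical"
      else if (hs == "ATTAAA") "variant_ATTAAA"
      else if (hs == "AATAAG") "variant_AATAAG"
      else if (mm == 1L) "one_mismatch"
      else next
    hits[[length(hits) + 1]] <- list(cls = cls, seq = hs, d = d, mm = mm)
  }
  ## tandem 10-mer: report as its own class when its 3' end is in-window
  tandem <- NULL
  if (n >= 10L) {
    for (i in seq_len(n - 9L)) {
      dec <- paste(chars[i:(i + 9L)], collapse = "")
      if (dec == "AATAAATAAA") {
        d <- max_up + 1L - (i + 4L + offset)
        if (d >= min_up && d <= max_up) {
          tandem <- list(cls = "tandem", seq = dec, d = d, mm = 0L)
          break
        }
      }
    }
  }
  if (!is.null(tandem)) {
    return(structure(list(motif_class = "tandem",
                          matched_sequence = tandem$seq,
                          distance_upstream = tandem$d, mismatches = 0),
                     class = "pas_motif_hit"))
  }
  if (!length(hits)) return(none)
  mms <- vapply(hits, `[[`, 0L, "mm")
  ds <- vapply(hits, `[[`, 0L, "d")
  modal <- params$pas_modal_distance
  best <- order(mms, abs(ds - modal), ds)[1]
  h <- hits[[best]]
  structure(list(motif_class = h$cls, matched_sequence = h$seq,
                 distance_upstream = h$d, mismatches = h$mm),
            class = "pas_motif_hit")
}

#' Assess internal-priming risk downstream of a cleavage site
#'
#' Apparent cleavage sites followed by genomic adenosine runs are likely
#' internal-priming artifacts rather than true poly(A) sites. A site is
#' flagged when a run of at least `min_a_run` consecutive A bases
#' (transcription-strand sense) starts within `window_down` bases
#' downstream, or when the A fraction over the downstream window reaches
#' `a_fraction`.
#'
#' @inheritParams scan_pas_motif
#' @param window_down downstream window length in bp.
#' @param min_a_run run-length threshold.
#' @param a_fraction alternative trigger on the window A fraction.
#' @return list of class `priming_assessment`: `flagged`, `max_a_run`
#'   (longest A run starting within the window, possibly extending past it),
#'   `a_fraction_in_window`.
#' @export
assess_internal_priming <- function(genome, chrom, cleavage_pos, strand = "+",
                                    window_down = 10L, min_a_run = 6L,
                                    a_fraction = 0.7) {
  extra <- max(30L, min_a_run)
  ss <- if (strand == "-") {
    .sense_seq(genome, chrom, cleavage_pos - window_down - extra,
               cleavage_pos - 1L, strand)
  } else {
    .sense_seq(genome, chrom, cleavage_pos + 1L,
               cleavage_pos + window_down + extra, strand)
  }
  chars <- strsplit(ss$seq, "")[[1]]
  if (!length(chars)) {
    return(structure(list(flagged = FALSE, max_a_run = 0L,
                          a_fraction_in_window = NA_real_),
                     class = "priming_assessment"))
  }
  win <- chars[seq_len(min(window_down, length(chars)))]
  a_frac <- mean(win == "A")
  ## runs of A; track the longest one starting inside the window
  r <- rle(chars == "A")
  starts <- cumsum(c(1, r$lengths))[seq_along(r$lengths)]
  a_runs <- which(r$values)
  in_window <- a_runs[starts[a_runs] <= window_down]
  max_run <- if (length(in_window)) max(r$lengths[in_window]) else 0L
  flagged <- max_run >= min_a_run || a_frac >= a_fraction
  structure(list(flagged = flagged, max_a_run = as.integer(max_run),
                 a_fraction_in_window = a_frac),
            class = "priming_assessment")
}

#' Per-frame stop-codon counts over an interval
#'
#' Counts TAA/TAG/TGA in each of the three reading frames of the given
#' strand. A region carrying stop codons in every frame is implausible as a
#' single protein-coding exon, which is the sequence check used when an
#' opposite-strand gene is hypothesized.
#'
#' @inheritParams scan_pas_motif
#' @param start,end interval bounds (1-based inclusive, `end - start >= 2`).
#' @return list: `per_frame` (integer vector of 3), `min_across_frames`.
#' @export
stop_codon_profile <- function(genome, chrom, start, end, strand = "+") {
  if (end - start + 1 < 3) stop("interval shorter than one codon")
  ss <- .sense_seq(genome, chrom, start, end, strand)
  chars <- strsplit(ss$seq, "")[[1]]
  stops <- c("TAA", "TAG", "TGA")
  per_frame <- vapply(0:2, function(f) {
    idx <- seq(1 + f, length(chars) - 2, by = 3)
    if (!length(idx)) return(0L)
    codons <- vapply(idx, function(i) paste(chars[i:(i + 2)], collapse = ""), "")
    sum(codons %in% stops)
  }, integer(1))
  list(per_frame = per_frame, min_across_frames = min(per_frame))
}

#' AT fraction of an interval
#'
#' `(#A + #T) / (interval length - #N)`; ambiguous bases are excluded from
#' numerator and denominator. All-N intervals return `NA` with a warning.
#'
#' @inheritParams stop_codon_profile
#' @return numeric fraction in `[0, 1]`, or `NA` for an all-N interval.
#' @export
at_fraction <- function(genome, chrom, start, end) {
  ss <- .sense_seq(genome, chrom, start, end, "+")
  chars <- strsplit(ss$seq, "")[[1]]
  informative <- chars[chars != "N"]
  if (!length(informative)) {
    warning("all-N interval: AT fraction undefined")
    return(NA_real_)
  }
  mean(informative %in% c("A", "T"))
}
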