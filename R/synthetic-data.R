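## Synthetic locus generator: self-contained test loci (genome, annotation,
## per-replicate 3'-end tracks, RNA-seq coverage and junctions, ESTs, sRNA)
## with ground truth, emulating the nine worked re-annotation classes.

.SCENARIOS <- c("simple_extension", "ambiguous_multi_peak",
                "curated_two_sites", "long_extension_past_window",
                "wrong_strand", "overlapping_convergent",
                "overlapping_models_broad_peak", "pri_mirna",
                "novel_short_feature")

#' Specify a synthetic scenario
#'
#' Defaults encode the study conditions each scenario emulates: 3'-end
#' positional jitter of at most 2 bp (discrete triangular), Poisson read
#' counts per site and replicate, Poisson background, lognormal RNA-seq
#' window non-uniformity, sparse strand-unreliable ESTs.
#'
#' @param scenario one of `r paste(.SCENARIOS, collapse=", ")`.
#' @param seed RNG seed; identical spec + seed reproduces outputs exactly.
#' @param n_replicates number of 3'-end replicates (default 3).
#' @param reads_per_site mean reads per planted site per replicate.
#' @param background_rate Poisson background per base per replicate.
#' @param noise_free when `TRUE`: exact counts, no jitter, no background.
#' @param est_strand_error probability an EST strand flag is flipped.
#' @param rnaseq_mean,rnaseq_sdlog lognormal window model for RNA-seq depth.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario, seed = 1L, n_replicates = 3L,
                          reads_per_site = 20, background_rate = 0.02,
                          noise_free = FALSE, est_strand_error = 0.1,
                          rnaseq_mean = 10, rnaseq_sdlog = 0.8) {
  scenario <- match.arg(scenario, .SCENARIOS)
  stopifnot(seed == as.integer(seed), n_replicates >= 1, reads_per_site >= 0,
            background_rate >= 0)
  structure(list(scenario = scenario, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 reads_per_site = reads_per_site,
                 background_rate = background_rate,
                 noise_free = isTRUE(noise_free),
                 est_strand_error = est_strand_error,
                 rnaseq_mean = rnaseq_mean, rnaseq_sdlog = rnaseq_sdlog),
            class = "scenario_spec")
}

## run expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

## --- sequence construction helpers ---------------------------------------

.random_dna <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c(0.28, 0.22, 0.22, 0.28))
}

## overwrite [from, to] with a neutral pattern containing no adenosine, so
## no poly(A)-signal (even at 1 mismatch) and no A run can occur there
.scrub <- function(chars, from, to, pattern = c("G", "C", "T", "G", "C", "C")) {
  idx <- from:to
  chars[idx] <- rep(pattern, length.out = length(idx))
  chars
}

.plant <- function(chars, at, motif) {
  m <- strsplit(motif, "")[[1]]
  chars[at:(at + length(m) - 1)] <- m
  chars
}

## plant a cleavage site's sequence context: neutral window, poly(A)-signal
## hexamer ending `dist` bp upstream (transcription sense), clean downstream
.plant_site_context <- function(chars, pos, strand, dist = 19L,
                                motif = "AATAAA") {
  w <- nchar(motif) - 1L
  if (strand == "-") {
    chars <- .scrub(chars, pos - 40, pos + 45 + w)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    chars <- .plant(chars, pos + dist, rc)
  } else {
    chars <- .scrub(chars, pos - 45 - w, pos + 40)
    chars <- .plant(chars, pos - dist - w, motif)
  }
  chars
}

## plant an internal-priming decoy: neutral upstream scan window (no
## signal; note an adenosine run itself is one mismatch from AATAAA, so
## decoys must sit > 50 bp apart to keep each other's windows clean), and a
## 10-base adenosine run immediately downstream
.plant_decoy_context <- function(chars, pos, strand) {
  if (strand == "-") {
    chars <- .scrub(chars, pos + 10, pos + 45)
    chars <- .plant(chars, pos - 10, paste(rep("T", 10), collapse = ""))
  } else {
    chars <- .scrub(chars, pos - 45, pos - 10)
    chars <- .plant(chars, pos + 1, paste(rep("A", 10), collapse = ""))
  }
  chars
}

## --- track builders -------------------------------------------------------

## discrete triangular jitter on -2..2, matching the +/-2 bp positional
## accuracy of 3'-end reads
.jitter <- function(n) {
  sample(-2:2, n, replace = TRUE, prob = c(1, 2, 3, 2, 1) / 9)
}

#' Simulate per-replicate 3'-end count tracks
#'
#' For each planted site, each replicate draws a Poisson number of reads at
#' the stated mean (exact counts in the noise-free limit), jitters each
#' read's 3' end by a discrete triangular offset on -2..+2, and adds
#' uniform Poisson background positions. This is the generative model the
#' peak caller is scored against.
#'
#' @param sites data.frame with `pos`, `strand`, `reads` (mean per
#'   replicate).
#' @param contig_len contig length in bp.
#' @param spec a [scenario_spec()] (supplies replicate count, noise flags,
#'   background rate).
#' @param chrom contig name.
#' @return list of `three_prime_track`, one per replicate.
#' @export
simulate_drs_tracks <- function(sites, contig_len, spec, chrom = "chrS") {
  lapply(seq_len(spec$n_replicates), function(rep_i) {
    rows <- list()
    for (s in seq_len(nrow(sites))) {
      mean_reads <- sites$reads[s]
      n <- if (spec$noise_free) round(mean_reads) else
        stats::rpois(1, mean_reads)
      if (n == 0) next
      pos <- rep(sites$pos[s], n)
      if (!spec$noise_free) pos <- pos + .jitter(n)
      rows[[length(rows) + 1]] <- data.frame(pos = pos,
                                             strand = sites$strand[s])
    }
    if (!spec$noise_free && spec$background_rate > 0) {
      for (st in c("+", "-")) {
        n_bg <- stats::rpois(1, spec$background_rate * contig_len / 2)
        if (n_bg > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            pos = sample.int(contig_len, n_bg, replace = TRUE), strand = st)
        }
      }
    }
    if (!length(rows)) {
      return(three_prime_track(
        data.frame(chrom = character(0), pos = numeric(0),
                   strand = character(0), count = numeric(0)),
        paste0("rep", rep_i)))
    }
    ends <- do.call(rbind, rows)
    key <- paste(ends$pos, ends$strand)
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(agg$key, " ", fixed = TRUE))
    tr <- data.frame(chrom = chrom, pos = as.numeric(parts[, 1]),
                     strand = parts[, 2], count = agg$Freq,
                     stringsAsFactors = FALSE)
    tr <- tr[order(tr$strand, tr$pos), , drop = FALSE]
    rownames(tr) <- NULL
    three_prime_track(tr, paste0("rep", rep_i))
  })
}

## RNA-seq depth over a contig: lognormal multipliers per 50 bp window over
## the expressed regions (floored at depth 1), explicit planted zero gaps
.make_rnaseq <- function(contig_len, expressed, gaps, spec, chrom = "chrS",
                         weak = NULL) {
  depth <- numeric(contig_len)
  fill <- function(depth, regions, mean_depth) {
    for (i in seq_len(nrow(regions))) {
      idx <- regions$start[i]:regions$end[i]
      wins <- ceiling(seq_along(idx) / 50)
      mult <- if (spec$noise_free) rep(1, max(wins)) else
        stats::rlnorm(max(wins), 0, spec$rnaseq_sdlog)
      depth[idx] <- pmax(1, round(mean_depth * mult[wins]))
    }
    depth
  }
  depth <- fill(depth, expressed, spec$rnaseq_mean)
  if (!is.null(weak) && nrow(weak)) depth <- fill(depth, weak, 2)
  if (!is.null(gaps) && nrow(gaps)) {
    for (i in seq_len(nrow(gaps))) depth[gaps$start[i]:gaps$end[i]] <- 0
  }
  coverage_vector(chrom, 1, depth, source = "RNA-seq")
}

## sparse ESTs as simple intervals with unreliable strand flags
.make_ests <- function(intervals, true_strand, spec, chrom = "chrS") {
  if (is.null(intervals) || !nrow(intervals)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      name = character(0)))
  }
  flip <- if (spec$noise_free) rep(FALSE, nrow(intervals)) else
    stats::runif(nrow(intervals)) < spec$est_strand_error
  strand <- ifelse(flip, ifelse(true_strand == "+", "-", "+"), true_strand)
  data.frame(chrom = chrom, start = intervals$start, end = intervals$end,
             strand = strand, name = sprintf("EST_%03d", seq_len(nrow(intervals))),
             stringsAsFactors = FALSE)
}

.est_coverage <- function(est, region, chrom = "chrS") {
  if (!nrow(est)) {
    return(coverage_vector(chrom, region[1],
                           numeric(region[2] - region[1] + 1), source = "EST"))
  }
  coverage_from_alignments(est, region, chrom = chrom, source = "EST")
}

## --- scenario builders ----------------------------------------------------

.build_simple_extension <- function(spec) {
  len <- 12000L; chrom <- "chrS"
  chars <- .random_dna(len)
  site_pos <- c(4450, 4900, 5400, 7200)
  for (p in site_pos) chars <- .plant_site_context(chars, p, "+", dist = 19L)
  gene <- gene_model("GENE1", data.frame(
    role = c("five_prime_utr", "exon", "exon", "three_prime_utr"),
    chrom = chrom, start = c(1001, 1001, 2101, 2901),
    end = c(1200, 1800, 3000, 3000), strand = "+"))
  sites <- data.frame(pos = site_pos, strand = "+",
                      reads = c(rep(spec$reads_per_site, 3),
                                spec$reads_per_site * 2))
  drs <- simulate_drs_tracks(sites, len, spec)
  rnaseq_gaps <- data.frame(start = c(1801, 5601, 6101, 6801),
                            end = c(2100, 5625, 6140, 6830))
  rnaseq <- .make_rnaseq(len, data.frame(start = 1001, end = 7201),
                         rnaseq_gaps, spec)
  junctions <- data.frame(chrom = chrom, donor = 1800, acceptor = 2101,
                          count = 10L)
  est <- .make_ests(data.frame(start = c(2800, 4400, 6000),
                               end = c(4600, 6200, 7210)), "+", spec)
  truth <- list(
    sites = data.frame(pos = site_pos, strand = "+", expected_accept = TRUE),
    planted_gaps = rnaseq_gaps[-1, ],
    expected_endpoint = "positive_extension",
    expected_path = 1:8)
  list(genome = .dna(chars, chrom), gene = gene, drs_tracks = drs,
       rnaseq = rnaseq, junctions = junctions, est = est, srna = NULL,
       truth = truth)
}

.build_ambiguous_multi_peak <- function(spec) {
  len <- 8000L; chrom <- "chrS"
  chars <- .random_dna(len)
  decoys <- c(2730, 2790, 2850, 2910)
  true_site <- 4200
  for (p in decoys) chars <- .plant_decoy_context(chars, p, "+")
  chars <- .plant_site_context(chars, true_site, "+", dist = 19L)
  gene <- gene_model("GENE2", data.frame(
    role = c("exon", "three_prime_utr"), chrom = chrom,
    start = c(1001, 2601), end = c(2700, 2700), strand = "+"))
  sites <- data.frame(pos = c(decoys, true_site), strand = "+",
                      reads = c(rep(10, 4), 30))
  drs <- simulate_drs_tracks(sites, len, spec)
  rnaseq <- .make_rnaseq(len, data.frame(start = 1001, end = 4201), NULL, spec)
  est <- .make_ests(data.frame(start = 2600, end = 4210), "+", spec)
  truth <- list(
    sites = data.frame(pos = c(decoys, true_site), strand = "+",
                       expected_accept = c(rep(FALSE, 4), TRUE)),
    decoys = decoys,
    expected_endpoint = "positive_extension",
    expected_path = 1:8)
  list(genome = .dna(chars, chrom), gene = gene, drs_tracks = drs,
       rnaseq = rnaseq, junctions = NULL, est = est, srna = NULL,
       truth = truth)
}

.build_curated_two_sites <- function(spec) {
  len <- 14000L; chrom <- "chrS"
  chars <- .random_dna(len)
  site_pos <- c(8500, 12000)
  dists <- c(19L, 24L)
  for (i in 1:2) {
    chars <- .plant_site_context(chars, site_pos[i], "+", dist = dists[i])
  }
  gene <- gene_model("SLFN5like", data.frame(
    role = c("five_prime_utr", "exon", "exon", "three_prime_utr"),
    chrom = chrom, start = c(1001, 1001, 2501, 3301),
    end = c(1300, 1600, 3500, 3500), strand = "+"))
  sites <- data.frame(pos = site_pos, strand = "+",
                      reads = c(spec$reads_per_site, spec$reads_per_site * 2))
  drs <- simulate_drs_tracks(sites, len, spec)
  rnaseq <- .make_rnaseq(len, data.frame(start = 1001, end = 12001),
                         data.frame(start = 1601, end = 2500), spec)
  junctions <- data.frame(chrom = chrom, donor = 1600, acceptor = 2501,
                          count = 8L)
  est <- .make_ests(data.frame(start = c(3200, 7800), end = c(8600, 12010)),
                    "+", spec)
  truth <- list(
    sites = data.frame(pos = site_pos, strand = "+", expected_accept = TRUE),
    motif_distances = dists,
    expected_endpoint = "positive_extension",
    expected_path = 1:8)
  list(genome = .dna(chars, chrom), gene = gene, drs_tracks = drs,
       rnaseq = rnaseq, junctions = junctions, est = est, srna = NULL,
       truth = truth)
}

.build_long_extension <- function(spec) {
  len <- 8000L; chrom <- "chrS"
  chars <- .random_dna(len)
  ## minus-strand gene: 3' direction is decreasing coordinate
  site_pos <- c(1400, 755)
  for (p in site_pos) chars <- .plant_site_context(chars, p, "-", dist = 19L)
  gene <- gene_model("AT4G02715like", data.frame(
    role = c("exon", "five_prime_utr"), chrom = chrom,
    start = c(2001, 2801), end = c(3100, 3100), strand = "-"))
  ## the distal site is a multi-peak cluster, as is common at plant loci
  sites <- data.frame(pos = c(site_pos, 760, 750), strand = "-",
                      reads = c(spec$reads_per_site, spec$reads_per_site * 2,
                                spec$reads_per_site / 2,
                                spec$reads_per_site / 2))
  drs <- simulate_drs_tracks(sites, len, spec)
  rnaseq <- .make_rnaseq(len, data.frame(start = 747, end = 3100), NULL, spec)
  est <- .make_ests(data.frame(start = c(750, 1900), end = c(2100, 3100)),
                    "-", spec)
  truth <- list(
    sites = data.frame(pos = site_pos, strand = "-", expected_accept = TRUE),
    baseline_window_detects = 0L,
    expected_endpoint = "positive_extension",
    expected_endpoint_baseline = "negative_insufficient")
  list(genome = .dna(chars, chrom), gene = gene, drs_tracks = drs,
       rnaseq = rnaseq, junctions = NULL, est = est, srna = NULL,
       truth = truth)
}

.build_wrong_strand <- function(spec) {
  len <- 4000L; chrom <- "chrS"
  chars <- .random_dna(len)
  ## broad minus-strand peak at the start of the annotated 5' UTR
  broad <- 2005:2024
  chars <- .plant_site_context(chars, 2014, "-", dist = 19L)
  ## minus-strand stop codons in all three frames over the gene body
  ## (plus-strand TTA at p reads as TAA on the reverse strand)
  for (p in c(2150, 2160, 2170, 2200, 2210, 2220)) {
    chars <- .plant(chars, p, "TTA")
  }
  gene <- gene_model("AT1G68945like", data.frame(
    role = c("five_prime_utr", "exon", "three_prime_utr"), chrom = chrom,
    start = c(2001, 2001, 2351), end = c(2120, 2400, 2400), strand = "+"))
  sites <- data.frame(pos = broad, strand = "-",
                      reads = rep(5, length(broad)))
  drs <- simulate_drs_tracks(sites, len, spec)
  rnaseq <- .make_rnaseq(len, data.frame(start = 2001, end = 2400), NULL, spec)
  est <- .make_ests(data.frame(start = 2001, end = 2400), "+", spec)
  truth <- list(
    broad_peak = c(min(broad), max(broad)),
    expected_endpoint_unstranded = "negative_inconsistent",
    expected_path_unstranded = c(1, 2, 3, 9, 10, 11, 12),
    expected_endpoint_stranded = "tentative_opposite_strand",
    expected_path_stranded = c(1, 2, 3, 9, 10, 13, 14, 15))
  list(genome = .dna(chars, chrom), gene = gene, drs_tracks = drs,
       rnaseq = rnaseq, junctions = NULL, est = est, srna = NULL,
       truth = truth)
}

.build_overlapping_convergent <- function(spec) {
  len <- 10000L; chrom <- "chrS"
  chars <- .random_dna(len)
  ## broad AT-rich terminal cluster at the annotated plus-strand gene end
  broad <- 3993:4008
  chars <- .scrub(chars, 3950, 4045)
  chars <- .plant(chars, 3950,
                  paste(rep(c("A", "T"), 21), collapse = ""))  # AT-rich upstream
  ## two weak distal plus-strand sites with the AATAAG variant signal
  for (p in c(4056, 4100)) {
    chars <- .plant_site_context(chars, p, "+", dist = 19L)
    chars <- .plant(chars, p - 19 - 5, "AATAAG")
  }
  ## convergent minus-strand gene with a site at its annotated end and one
  ## further downstream (decreasing coordinate)
  for (p in c(5501, 4300)) {
    chars <- .plant_site_context(chars, p, "-", dist = 20L)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("AATAAG")))
    chars <- .plant(chars, p + 20, rc)
  }
  geneA <- gene_model("RPL31like", data.frame(
    role = c("exon", "three_prime_utr"), chrom = chrom,
    start = c(1001, 3801), end = c(4000, 4000), strand = "+"))
  geneB <- gene_model("TBC1D8like", data.frame(
    role = c("exon", "three_prime_utr"), chrom = chrom,
    start = c(5501, 5501), end = c(9000, 5700), strand = "-"))
  sites <- rbind(
    data.frame(pos = broad, strand = "+", reads = rep(6, length(broad))),
    data.frame(pos = c(4056, 4100), strand = "+", reads = c(12, 12)),
    data.frame(pos = c(5501, 4300), strand = "-",
               reads = c(spec$reads_per_site, 20)))
  drs <- simulate_drs_tracks(sites, len, spec)
  rnaseq <- .make_rnaseq(len, data.frame(start = 1001, end = 9000), NULL, spec)
  est <- .make_ests(data.frame(start = c(1001, 5501), end = c(4010, 9000)),
                    c("+", "-"), spec)
  ## un-stranded coverage runs straight into the convergent gene, so the
  ## terminus of the plus-strand evidence cannot be pinned to its cluster:
  ## exactly the ambiguity this region class exhibits
  truth <- list(
    broad_peak = c(min(broad), max(broad)),
    at_rich_upstream = c(3950, 3991),
    variant_sites = c(4056, 4100),
    expected_endpoint = "tentative_extension")
  list(genome = .dna(chars, chrom), gene = geneA, genes = list(geneA, geneB),
       drs_tracks = drs, rnaseq = rnaseq, junctions = NULL, est = est,
       srna = NULL, truth = truth)
}

.build_overlapping_models <- function(spec) {
  len <- 9000L; chrom <- "chrS"
  chars <- .random_dna(len)
  ## short-3'-UTR site 13 bp downstream of the plus-strand stop codon,
  ## with the ATTAAA variant signal 17 bp upstream
  site_f <- 4313
  chars <- .plant_site_context(chars, site_f, "+", dist = 17L,
                               motif = "ATTAAA")
  ## antisense gene overlapping completely, with its own 3'-end site
  ## coincident with its annotated end
  site_r <- 1505
  chars <- .plant_site_context(chars, site_r, "-", dist = 19L)
  geneF <- gene_model("METTL12like", data.frame(
    role = c("exon", "three_prime_utr"), chrom = chrom,
    start = c(2001, 4301), end = c(4500, 4500), strand = "+"))
  geneR <- gene_model("C11orf48like", data.frame(
    role = "exon", chrom = chrom, start = 1501, end = 5200, strand = "-"))
  sites <- data.frame(pos = c(site_f, site_r), strand = c("+", "-"),
                      reads = c(8, spec$reads_per_site))
  drs <- simulate_drs_tracks(sites, len, spec)
  rnaseq <- .make_rnaseq(len, data.frame(start = 1501, end = 5200), NULL, spec)
  est <- .make_ests(data.frame(start = 1501, end = 5200), "-", spec)
  truth <- list(
    forward_site = site_f, reverse_site = site_r,
    forward_motif_class = "variant_ATTAAA", forward_motif_distance = 17L,
    expected_endpoint_forward = "negative_insufficient",
    expected_endpoint_reverse = "positive_structure_confirmed")
  list(genome = .dna(chars, chrom), gene = geneF, genes = list(geneF, geneR),
       drs_tracks = drs, rnaseq = rnaseq, junctions = NULL, est = est,
       srna = NULL, truth = truth)
}

.build_pri_mirna <- function(spec) {
  len <- 6000L; chrom <- "chrS"
  chars <- .random_dna(len)
  cluster_pos <- 2777
  chars <- .scrub(chars, cluster_pos - 45, cluster_pos + 40)
  chars <- .plant(chars, cluster_pos - 26 - 9, "AATAAATAAA")  # tandem signal
  arms <- data.frame(start = c(2001, 2056, 2501, 2556),
                     end = c(2022, 2077, 2522, 2577),
                     height = c(100, 900, 120, 950))
  srna_depth <- numeric(len)
  for (i in seq_len(nrow(arms))) {
    srna_depth[arms$start[i]:arms$end[i]] <- arms$height[i]
  }
  srna <- coverage_vector(chrom, 1, srna_depth, source = "sRNA")
  rnaseq_blocks <- data.frame(start = c(1700, 2085, 2585),
                              end = c(1995, 2495, 2780))
  depth <- numeric(len)
  for (i in seq_len(nrow(rnaseq_blocks))) {
    depth[rnaseq_blocks$start[i]:rnaseq_blocks$end[i]] <- 6
  }
  rnaseq <- coverage_vector(chrom, 1, depth, source = "RNA-seq")
  gene <- gene_model("MIR200C141like", data.frame(
    role = "exon", chrom = chrom, start = 1700, end = 2780, strand = "+"))
  sites <- data.frame(pos = cluster_pos, strand = "+",
                      reads = spec$reads_per_site)
  drs <- simulate_drs_tracks(sites, len, spec)
  truth <- list(
    arm_pairs = list(
      list(five_p = c(2001, 2022), three_p = c(2056, 2077), dominant = "3p"),
      list(five_p = c(2501, 2522), three_p = c(2556, 2577), dominant = "3p")),
    cluster_pos = cluster_pos,
    tandem_motif_distance = 26L,
    excision_gaps = data.frame(start = c(1996, 2496), end = c(2084, 2584)))
  list(genome = .dna(chars, chrom), gene = gene, drs_tracks = drs,
       rnaseq = rnaseq, junctions = NULL,
       est = .make_ests(NULL, "+", spec), srna = srna, truth = truth)
}

.build_novel_short_feature <- function(spec) {
  len <- 6000L; chrom <- "chrS"
  chars <- .random_dna(len)
  gene <- gene_model("AT4G10810like", data.frame(
    role = c("exon", "three_prime_utr"), chrom = chrom,
    start = c(1001, 1901), end = c(2000, 2000), strand = "+"))
  weak_sites <- seq(2400, 2800, by = 100)
  for (p in weak_sites) chars <- .scrub(chars, p - 45, p + 40)
  sites <- data.frame(pos = weak_sites, strand = "+",
                      reads = rep(15, length(weak_sites)))
  drs <- simulate_drs_tracks(sites, len, spec)
  depth <- numeric(len)
  depth[1001:2000] <- 8
  depth[2301:2900] <- 3   # separated low-level block
  rnaseq <- coverage_vector(chrom, 1, depth, source = "RNA-seq")
  srna_depth <- numeric(len)
  srna_depth[2450:2480] <- 500   # single peak, no arm-pair structure
  srna <- coverage_vector(chrom, 1, srna_depth, source = "sRNA")
  truth <- list(
    separation = c(2001, 2300),
    block = c(2301, 2900),
    srna_peak = c(2450, 2480),
    n_weak_sites = length(weak_sites),
    expected_endpoint = "tentative_novel_feature",
    expected_path = c(1, 2, 3, 4, 21),
    external_prediction = c(2440, 2490))
  list(genome = .dna(chars, chrom), gene = gene, drs_tracks = drs,
       rnaseq = rnaseq, junctions = NULL, est = .make_ests(NULL, "+", spec),
       srna = srna, truth = truth)
}

.dna <- function(chars, chrom) {
  gs <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(gs) <- chrom
  gs
}

#' Generate a synthetic scenario with ground truth
#'
#' Builds a self-contained locus: genome sequence with planted
#' poly(A)-signal motifs and internal-priming decoys, gene annotation,
#' per-replicate 3'-end count tracks (jittered, Poisson, with background),
#' RNA-seq coverage and junctions, ESTs with unreliable strand flags, sRNA
#' coverage where relevant, and a truth record sufficient to score every
#' pipeline stage. Reproducible: identical spec and seed give identical
#' output.
#'
#' @param spec a [scenario_spec()] (or a scenario name, with `seed`).
#' @param seed used when `spec` is a scenario name.
#' @return list of class `scenario` with elements `genome`, `gene`
#'   (and `genes` for multi-gene scenarios), `drs_tracks`, `rnaseq`,
#'   `junctions`, `est`, `srna`, `truth`, `spec`.
#' @export
generate_scenario <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- scenario_spec(spec, seed = seed)
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$scenario == "ambiguous_multi_peak" && !spec$noise_free) {
    ## motif/priming discrimination is defined in the noise-free limit
    spec$noise_free <- TRUE
  }
  builder <- switch(spec$scenario,
    simple_extension = .build_simple_extension,
    ambiguous_multi_peak = .build_ambiguous_multi_peak,
    curated_two_sites = .build_curated_two_sites,
    long_extension_past_window = .build_long_extension,
    wrong_strand = .build_wrong_strand,
    overlapping_convergent = .build_overlapping_convergent,
    overlapping_models_broad_peak = .build_overlapping_models,
    pri_mirna = .build_pri_mirna,
    novel_short_feature = .build_novel_short_feature)
  scn <- .with_seed(spec$seed, builder(spec))
  scn$spec <- spec
  class(scn) <- "scenario"
  scn
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s' (seed %d): contig %s of %d bp, %d replicate(s)\n",
              x$spec$scenario, x$spec$seed, names(x$genome)[1],
              Biostrings::width(x$genome)[1], length(x$drs_tracks)))
  invisible(x)
}
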