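make_aln <- function(...) {
  df <- data.frame(...)
  if (is.null(df$chrom)) df$chrom <- "chrS"
  df
}

test_that("read filter applies the uniqueness/indel/length rules exactly", {
  aln <- make_aln(
    start = c(100, 100, 100, 100, 100),
    end = c(130, 130, 150, 124, 125),
    strand = "+",
    unique = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    n_indels = c(3, 4, 0, 0, 0),
    read_length = c(30, 30, 50, 24, 25))
  res <- filter_reads(aln)
  ## retained: 3 indels/30 bp; and the boundary 25 bp read (inclusive)
  expect_equal(nrow(res$alignments), 2)
  expect_equal(res$alignments$end, c(130, 125))
  expect_equal(res$stats$removed_indels, 1)     # 4 indels
  expect_equal(res$stats$removed_nonunique, 1)  # multi-mapper
  expect_equal(res$stats$removed_short, 1)      # 24 bp
})

test_that("indels and read length are derived from cigar when absent", {
  aln <- make_aln(start = c(100, 100, 100), end = c(129, 129, 129),
                  strand = "+", unique = TRUE,
                  cigar = c("30M", "10M2I2D18M", NA))
  expect_warning(res <- filter_reads(aln), "cigar")
  expect_equal(res$stats$removed_no_cigar, 1)
  ## 2I + 2D = 4 indels exceeds the default threshold of 3; only the
  ## clean 30M alignment survives
  expect_equal(res$stats$removed_indels, 1)
  expect_equal(nrow(res$alignments), 1)
  expect_equal(res$alignments$n_indels, 0)
  expect_equal(res$alignments$read_length, 30)
})

test_that("uniqueness falls back to mapq and secondary flags", {
  aln <- make_aln(start = 100, end = c(130, 130, 130), strand = "+",
                  n_indels = 0, read_length = 30,
                  mapq = c(60, 10, 60), secondary = c(FALSE, FALSE, TRUE))
  res <- filter_reads(aln)
  expect_equal(nrow(res$alignments), 1)
})

test_that("3'-end counting uses the strand-appropriate terminal base", {
  aln <- make_aln(start = c(100, 100, 120, 121), end = c(130, 130, 130, 130),
                  strand = c("+", "-", "+", "+"))
  tr <- count_three_prime_ends(aln)
  plus <- tr[tr$strand == "+", ]
  expect_equal(plus$pos, 130)
  expect_equal(plus$count, 3)      # additive over reads ending at 130
  minus <- tr[tr$strand == "-", ]
  expect_equal(minus$pos, 100)     # minus-strand 3' end is the lowest base
  expect_equal(minus$count, 1)
  expect_equal(sum(tr$count), nrow(aln))  # totals conserved
})

track_from_counts <- function(counts, pos = 1000, rep_id = "rep1") {
  three_prime_track(data.frame(chrom = "chrS", pos = pos, strand = "+",
                               count = counts), rep_id)
}

test_that("replicate filter retains (3,3,3) at snr 3 and drops weaker sets", {
  tracks <- lapply(1:3, function(i) track_from_counts(3, rep_id = paste0("r", i)))
  res <- replicate_position_filter(tracks)
  expect_equal(nrow(res), 1)
  expect_equal(res$total, 9)
  expect_identical(res$snr, 3)   # 9 / sqrt(9), exactly

  t2 <- list(track_from_counts(3, rep_id = "r1"),
             track_from_counts(3, rep_id = "r2"),
             track_from_counts(2, rep_id = "r3"))
  expect_equal(nrow(replicate_position_filter(t2)), 0)

  t3 <- list(track_from_counts(9, rep_id = "r1"),
             three_prime_track(data.frame(chrom = character(0),
                                          pos = numeric(0),
                                          strand = character(0),
                                          count = numeric(0)), "r2"),
             three_prime_track(data.frame(chrom = character(0),
                                          pos = numeric(0),
                                          strand = character(0),
                                          count = numeric(0)), "r3"))
  expect_equal(nrow(replicate_position_filter(t3)), 0)

  expect_error(replicate_position_filter(list()), "zero replicate")
})

test_that("singleton mode keeps multi-read positions of a single replicate", {
  tr <- three_prime_track(data.frame(chrom = "chrS", pos = c(10, 20),
                                     strand = "+", count = c(1, 2)), "r1")
  res <- replicate_position_filter(list(tr),
                                   pipeline_config(singleton_mode = TRUE))
  expect_equal(res$pos, 20)
  expect_error(
    replicate_position_filter(list(tr, tr),
                              pipeline_config(singleton_mode = TRUE)),
    "single-replicate")
})

test_that("raising the per-replicate threshold never enlarges the retained set", {
  set.seed(4101)
  for (rep in 1:250) {
    counts <- matrix(rpois(12, 3), nrow = 3)   # 3 replicates x 4 positions
    tracks <- lapply(1:3, function(i) {
      keep <- counts[i, ] > 0
      three_prime_track(data.frame(chrom = "chrS",
                                   pos = (1:4 * 100)[keep], strand = "+",
                                   count = counts[i, keep]),
                        paste0("r", i))
    })
    prev <- NULL
    for (thr in 1:5) {
      res <- replicate_position_filter(
        tracks, pipeline_config(min_reads_per_replicate = thr, snr_min = NA))
      if (!is.null(prev)) expect_true(all(res$pos %in% prev))
      prev <- res$pos
    }
  }
})

test_that("clustering matches a brute-force connected-components oracle", {
  set.seed(4102)
  for (rep in 1:25) {
    n <- sample(1:50, 1)
    pos <- sort(sample.int(2000, n))
    gap <- sample(c(1, 5, 25, 30, 100), 1)
    df <- data.frame(chrom = "chrS", pos = pos, strand = "+",
                     total = rpois(n, 5) + 1)
    got <- cluster_peaks(df, max_cluster_gap = gap)
    want <- oracle_cluster(pos, gap)
    expect_equal(nrow(got), length(unique(want)))
    ## conservation of counts through clustering
    expect_equal(sum(got$total_count), sum(df$total))
    ## every member set matches an oracle component
    for (i in seq_len(nrow(got))) {
      mem <- got$members[[i]]$pos
      expect_true(all(want[match(mem, pos)] == want[match(mem[1], pos)]))
    }
  }
})

test_that("cluster structure mirrors the published peak descriptions", {
  ## three separated positions within 30 bp form one cluster of three
  ## subpeaks; the mode is the highest-count member
  df <- data.frame(chrom = "chrS", pos = c(100, 112, 125), strand = "-",
                   total = c(5, 3, 6))
  got <- cluster_peaks(df, max_cluster_gap = 30)
  expect_equal(nrow(got), 1)
  expect_equal(got$subpeak_count, 3)
  expect_equal(got$mode, 125)
  ## adjacent bases with one summit form a single subpeak
  df_adj <- data.frame(chrom = "chrS", pos = 100:104, strand = "+",
                       total = c(2, 4, 9, 4, 2))
  got_adj <- cluster_peaks(df_adj, max_cluster_gap = 25)
  expect_equal(got_adj$subpeak_count, 1)
  expect_equal(got_adj$mode, 102)

  ## two positions 100 bp apart split at a 25 bp gap
  df2 <- data.frame(chrom = "chrS", pos = c(100, 200), strand = "+",
                    total = c(4, 4))
  expect_equal(nrow(cluster_peaks(df2, max_cluster_gap = 25)), 2)

  ## singleton cluster has zero span
  df3 <- data.frame(chrom = "chrS", pos = 500, strand = "+", total = 9)
  got3 <- cluster_peaks(df3, max_cluster_gap = 25)
  expect_equal(got3$end - got3$start, 0)
  expect_equal(got3$snr, 3)

  ## count ties resolve towards the transcriptionally distal position
  df4 <- data.frame(chrom = "chrS", pos = c(100, 105), strand = "+",
                    total = c(7, 7))
  expect_equal(cluster_peaks(df4, max_cluster_gap = 25)$mode, 105)
  df4$strand <- "-"
  expect_equal(cluster_peaks(df4, max_cluster_gap = 25)$mode, 100)
})

test_that("planted sites are recovered with modes within 2 bp, no background", {
  scn <- get_scenario("simple_extension", seed = 11)
  positions <- replicate_position_filter(scn$drs_tracks)
  clusters <- cluster_peaks(positions)
  expect_equal(nrow(clusters), nrow(scn$truth$sites))
  expect_true(all(abs(sort(clusters$mode) - sort(scn$truth$sites$pos)) <= 2))
  expect_true(all(clusters$strand == "+"))
})
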