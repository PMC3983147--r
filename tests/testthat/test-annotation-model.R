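test_that("interval lengths reproduce every published per-segment value", {
  tab <- read.delim(system.file("extdata", "reannotation_table_rows.tsv",
                                package = "threeprime"))
  expect_gte(nrow(tab), 20)
  for (i in seq_len(nrow(tab))) {
    gi <- genome_interval(tab$chrom[i], tab$start[i], tab$end[i],
                          tab$strand[i])
    expect_identical(paper_length(gi), as.numeric(tab$coverage_bp[i]),
                     label = paste("row", tab$table[i], tab$label[i]))
  }
})

test_that("interval normalization handles display order and degenerates", {
  gi <- genome_interval("2", 32572160, 32570321, "-")  # printed high-to-low
  expect_true(gi$display_rev)
  expect_equal(c(gi$start, gi$end), c(32570321, 32572160))
  ## idempotent: re-normalizing an already normalized interval changes nothing
  gi2 <- genome_interval(gi$chrom, gi$start, gi$end, gi$strand)
  expect_false(gi2$display_rev)
  expect_equal(c(gi2$start, gi2$end), c(gi$start, gi$end))
  ## degenerate point interval has zero length
  expect_equal(paper_length(genome_interval("1", 100, 100)), 0)
  expect_error(genome_interval("1", 0, 10), "start")
})

test_that("bed conversion round-trips through the centralized pair", {
  b <- to_bed_coords(3546262, 3585602)
  expect_equal(b$start, 3546261)
  back <- from_bed_coords(b$start, b$end)
  expect_equal(c(back$start, back$end), c(3546262, 3585602))
})

test_that("re-annotation summaries are segment sums, with span kept apart", {
  bmpr1a <- data.frame(
    role = c("five_prime_utr", "body", "three_prime_utr"), chrom = "6",
    start = c(3546262, 3564180, 3585586), end = c(3564179, 3585585, 3590064),
    strand = "+")
  rec <- build_reannotation_record("BMPR1A", bmpr1a)
  expect_equal(rec$summary_length_bp, 43800)
  expect_equal(rec$span_bp, 43802)  # span and segment sum legitimately differ
  expect_equal(rec$summary_interval$start, 3546262)
  expect_equal(rec$summary_interval$end, 3590064)

  hoxa7 <- data.frame(
    role = c("five_prime_utr", "body", "three_prime_utr"), chrom = "2",
    start = c(32572292, 32572159, 32570321),   # minus strand, printed order
    end = c(32572160, 32570322, 32568768),
    strand = "-")
  rec2 <- build_reannotation_record("HOXA7", hoxa7)
  expect_equal(rec2$summary_length_bp, 3522)

  single <- build_reannotation_record("X", data.frame(
    role = "body", chrom = "1", start = 100, end = 175, strand = "+"))
  expect_equal(single$summary_length_bp, 75)

  ## the C11orf83 case: its published summary equals the span, not the sum
  c11 <- build_reannotation_record("C11orf83", data.frame(
    role = c("five_prime_utr", "body", "three_prime_utr"), chrom = "11",
    start = c(62439125, 62439217, 62439585),
    end = c(62439216, 62439584, 62439844), strand = "+"))
  expect_equal(c11$span_bp, 719)
  expect_equal(c11$summary_length_bp, 717)
})

test_that("malformed segment sets are rejected", {
  expect_error(build_reannotation_record("X", data.frame(
    role = c("body", "three_prime_utr"), chrom = "1",
    start = c(100, 250), end = c(200, 300), strand = "+")),
    "abut")
  expect_error(build_reannotation_record("X", data.frame(
    role = c("body", "three_prime_utr"), chrom = "1",
    start = c(100, 201), end = c(200, 300), strand = c("+", "-"))),
    "strand")
  expect_error(gene_model("X", data.frame(
    role = c("exon", "exon"), chrom = "1", start = c(100, 150),
    end = c(200, 250), strand = "+")), "overlap")
})

test_that("annotations round-trip through GFF3 with exact coordinates", {
  gm <- gene_model("GENEX", data.frame(
    role = c("five_prime_utr", "exon", "exon", "three_prime_utr"),
    chrom = "chrS", start = c(1001, 1001, 2101, 2901),
    end = c(1200, 1800, 3000, 3000), strand = "+"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotations(gm, path, "GFF3")
  expect_equal(readLines(path)[1], "##gff-version 3")
  back <- read_annotations(path, "GFF3")
  expect_length(back, 1)
  seg_in <- gm$segments[order(gm$segments$start, gm$segments$role),
                        c("role", "start", "end")]
  seg_out <- back[[1]]$segments[order(back[[1]]$segments$start,
                                      back[[1]]$segments$role),
                                c("role", "start", "end")]
  rownames(seg_in) <- rownames(seg_out) <- NULL
  expect_equal(seg_out, seg_in)
  expect_equal(back[[1]]$strand, "+")
})

test_that("BED12 input converts with the documented coordinate shift", {
  ## hand-converted record: 0-based chromStart 999 = 1-based 1000; two
  ## blocks of 100 bp at offsets 0 and 500
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("chrS", 999, 1699, "est1", 0, "-", 999, 1699, 0, 2,
                   "100,200", "0,500", sep = "\t"), path)
  models <- read_annotations(path, "BED12")
  seg <- models[[1]]$segments
  expect_equal(seg$start, c(1000, 1500))
  expect_equal(seg$end, c(1099, 1699))
  expect_equal(models[[1]]$strand, "-")
})

test_that("TSV table output reproduces the published column layout", {
  rec <- build_reannotation_record("HOXA7", data.frame(
    role = c("five_prime_utr", "body", "three_prime_utr"), chrom = "2",
    start = c(32572292, 32572159, 32570321),
    end = c(32572160, 32570322, 32568768), strand = "-",
    evidence = c("EST/RNA-seq", "EST/RNA-seq", "DRS/EST/RNA-seq")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(rec, path, "TSV-table")
  tab <- read.delim(path)
  expect_equal(names(tab),
               c("annotation", "chr", "start", "end", "strand", "coverage_bp"))
  expect_equal(tab$coverage_bp[tab$annotation == "Summary"], 3522)
  utr <- tab[grepl("three_prime_utr", tab$annotation), ]
  expect_equal(utr$coverage_bp, 1553)
})
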