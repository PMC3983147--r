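## A 200 bp scaffold with no adenosine outside planted motifs, so planted
## signals are the only hits possible.
scaffold <- function(len = 200) {
  paste(rep(c("G", "C", "T", "G", "C", "C"), length.out = len), collapse = "")
}

plant_in <- function(seq, at, motif) {
  paste0(substr(seq, 1, at - 1), motif,
         substr(seq, at + nchar(motif), nchar(seq)))
}

test_that("canonical and variant signals are found at their distances", {
  pos <- 150
  ## AATAAA ending 19 bp upstream of the cleavage position
  g <- make_genome(list(chrS = plant_in(scaffold(), pos - 19 - 5, "AATAAA")))
  hit <- scan_pas_motif(g, "chrS", pos, "+")
  expect_equal(hit$motif_class, "canonical")
  expect_equal(hit$distance_upstream, 19)
  expect_equal(hit$mismatches, 0)

  ## ATTAAA ending 17 bp upstream is reported as the named variant
  g2 <- make_genome(list(chrS = plant_in(scaffold(), pos - 17 - 5, "ATTAAA")))
  hit2 <- scan_pas_motif(g2, "chrS", pos, "+")
  expect_equal(hit2$motif_class, "variant_ATTAAA")
  expect_equal(hit2$distance_upstream, 17)
  expect_equal(hit2$mismatches, 1)

  ## AATAAG named variant
  g3 <- make_genome(list(chrS = plant_in(scaffold(), pos - 20 - 5, "AATAAG")))
  expect_equal(scan_pas_motif(g3, "chrS", pos, "+")$motif_class,
               "variant_AATAAG")

  ## tandem AATAAATAAA reported as its own class
  g4 <- make_genome(list(chrS = plant_in(scaffold(), pos - 26 - 9,
                                         "AATAAATAAA")))
  hit4 <- scan_pas_motif(g4, "chrS", pos, "+")
  expect_equal(hit4$motif_class, "tandem")
  expect_equal(hit4$distance_upstream, 26)

  ## adenosine-free sequence yields no hit
  expect_equal(scan_pas_motif(make_genome(list(chrS = scaffold())),
                              "chrS", pos, "+")$motif_class, "none")
})

test_that("motif scan equals the exhaustive Hamming-<=1 oracle", {
  set.seed(4201)
  for (rep in 1:20) {
    seq_chars <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
    g <- make_genome(list(chrS = paste(seq_chars, collapse = "")))
    pos <- sample(60:950, 1)
    got <- scan_pas_motif(g, "chrS", pos, "+", window = c(10, 40))
    want <- oracle_pas_scan(seq_chars, pos, 10, 40)
    if (!length(want)) {
      expect_equal(got$motif_class, "none")
    } else {
      best_mm <- min(vapply(want, `[[`, 0, "mm"))
      expect_equal(got$mismatches, best_mm)
      ## the reported hit must be one of the oracle's minimal-mismatch hits,
      ## at the distance closest to 19
      cand <- Filter(function(h) h$mm == best_mm, want)
      dists <- vapply(cand, `[[`, 0, "d")
      expect_equal(abs(got$distance_upstream - 19), min(abs(dists - 19)))
    }
  }
})

test_that("minus-strand scanning mirrors the reverse complement", {
  set.seed(4202)
  seq_chars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  fwd <- paste(seq_chars, collapse = "")
  rcv <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  g <- make_genome(list(chrS = fwd))
  g_rc <- make_genome(list(chrS = rcv))
  for (pos in c(100, 200, 300)) {
    minus <- scan_pas_motif(g, "chrS", pos, "-")
    mirrored <- scan_pas_motif(g_rc, "chrS", 400 - pos + 1, "+")
    expect_equal(minus$motif_class, mirrored$motif_class)
    expect_equal(minus$distance_upstream, mirrored$distance_upstream)
  }
})

test_that("windows containing N never yield motif hits over the N run", {
  base <- scaffold()
  withN <- plant_in(base, 150 - 19 - 5, "AATNAA")  # N inside the hexamer
  g <- make_genome(list(chrS = withN))
  expect_equal(scan_pas_motif(g, "chrS", 150, "+")$motif_class, "none")
})

test_that("off-contig windows warn and truncate", {
  g <- make_genome(list(chrS = plant_in(scaffold(60), 10, "AATAAA")))
  expect_warning(hit <- scan_pas_motif(g, "chrS", 34, "+"), "truncated")
  expect_equal(hit$motif_class, "canonical")
})

test_that("internal priming flags adenosine runs and respects the boundary", {
  pos <- 100
  runA <- plant_in(scaffold(), pos + 1, strrep("A", 10))
  res <- assess_internal_priming(make_genome(list(chrS = runA)), "chrS", pos)
  expect_true(res$flagged)
  expect_equal(res$max_a_run, 10)

  clean <- plant_in(scaffold(), pos + 1, "ACGTACGTAC")
  res2 <- assess_internal_priming(make_genome(list(chrS = clean)), "chrS", pos)
  expect_false(res2$flagged)

  ## run of exactly min_a_run - 1 does not trigger
  short_run <- plant_in(scaffold(), pos + 1, strrep("A", 5))
  res3 <- assess_internal_priming(make_genome(list(chrS = short_run)),
                                  "chrS", pos, min_a_run = 6)
  expect_false(res3$flagged)
  expect_equal(res3$max_a_run, 5)

  ## A-rich window triggers the fraction rule even without a long run
  frac <- plant_in(scaffold(), pos + 1, "AACAACAACA")
  res4 <- assess_internal_priming(make_genome(list(chrS = frac)), "chrS",
                                  pos, a_fraction = 0.7)
  expect_true(res4$flagged)

  ## minus strand: run upstream in genome coordinates, downstream in sense
  runT <- plant_in(scaffold(), pos - 10, strrep("T", 10))
  res5 <- assess_internal_priming(make_genome(list(chrS = runT)), "chrS",
                                  pos, strand = "-")
  expect_true(res5$flagged)
})

test_that("stop codons are counted per frame on the requested strand", {
  g <- make_genome(list(chrS = paste0("TAATAGTGA", strrep("C", 30))))
  prof <- stop_codon_profile(g, "chrS", 1, 9, "+")
  expect_equal(prof$per_frame[1], 3)

  polyc <- make_genome(list(chrS = strrep("C", 60)))
  expect_equal(stop_codon_profile(polyc, "chrS", 1, 60, "+")$per_frame,
               c(0L, 0L, 0L))
  expect_error(stop_codon_profile(polyc, "chrS", 1, 2, "+"), "codon")
})

test_that("stop profile equals a brute-force six-frame oracle", {
  set.seed(4203)
  for (rep in 1:10) {
    chars <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
    g <- make_genome(list(chrS = paste(chars, collapse = "")))
    for (strand in c("+", "-")) {
      sense <- if (strand == "-") {
        strsplit(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(paste(chars, collapse = "")))), "")[[1]]
      } else chars
      want <- vapply(0:2, function(f) {
        idx <- seq(1 + f, length(sense) - 2, by = 3)
        sum(vapply(idx, function(i)
          paste(sense[i:(i + 2)], collapse = "") %in%
            c("TAA", "TAG", "TGA"), logical(1)))
      }, integer(1))
      got <- stop_codon_profile(g, "chrS", 1, 120, strand)
      expect_equal(got$per_frame, want)
      expect_equal(got$min_across_frames, min(want))
    }
  }
})

test_that("AT fraction excludes ambiguous bases", {
  g <- make_genome(list(chrS = "AATTGGCCNNNN"))
  expect_equal(at_fraction(g, "chrS", 1, 8), 0.5)
  expect_equal(at_fraction(g, "chrS", 1, 4), 1.0)
  expect_equal(at_fraction(g, "chrS", 5, 8), 0.0)
  ## N excluded from both numerator and denominator
  expect_equal(at_fraction(g, "chrS", 1, 12), 0.5)
  expect_warning(res <- at_fraction(g, "chrS", 9, 12), "all-N")
  expect_true(is.na(res))
})
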