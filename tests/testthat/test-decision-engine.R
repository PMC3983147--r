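## Minimal hand-built evidence bundles for tree-path checks.

mk_cluster <- function(mode, total = 60, strand = "+", motif = "canonical",
                       priming = FALSE, chrom = "chrS") {
  data.frame(chrom = chrom, start = mode, end = mode, strand = strand,
             mode = mode, total_count = total, snr = sqrt(total),
             n_positions = 1L, subpeak_count = 1L, motif_class = motif,
             motif_seq = "AATAAA", motif_distance = 19,
             motif_mismatches = 0, priming_flagged = priming,
             max_a_run = if (priming) 10L else 0L,
             stringsAsFactors = FALSE)
}

mk_bridge <- function(status = "continuous", offset = -1,
                      union_continuous = TRUE) {
  structure(list(status = status,
                 gaps = data.frame(), union_gaps = data.frame(),
                 union_continuous = union_continuous,
                 terminus_offset = offset, covered_frac = 1),
            class = "bridge_verdict")
}

simple_gene <- gene_model("G", data.frame(
  role = c("exon", "three_prime_utr"), chrom = "chrS",
  start = c(1000, 2901), end = c(3000, 3000), strand = "+"))

test_that("the endpoint set has exactly 3 positive, 3 tentative, 2 negative", {
  ep <- decision_endpoints()
  expect_length(ep, 8)
  expect_equal(sum(ep == "positive"), 3)
  expect_equal(sum(ep == "tentative"), 3)
  expect_equal(sum(ep == "negative"), 2)
})

test_that("a clean extension follows the eight-node positive path", {
  ev <- locus_evidence(simple_gene,
                       downstream_clusters = mk_cluster(7200),
                       bridges = list(mk_bridge()),
                       evidence_extends = TRUE)
  d <- evaluate_locus(ev)
  expect_equal(d$node_path, 1:8)
  expect_equal(d$endpoint, "positive_extension")
  expect_false(is.null(d$proposal))
  ## the proposal places the cluster mode at the proposed 3' UTR end
  utr <- d$proposal$segments[d$proposal$segments$role == "three_prime_utr", ]
  expect_equal(utr$end, 7200)
  expect_equal(utr$start, 3001)   # abuts the existing annotation end + 1
})

test_that("opposite-strand evidence follows the two described paths", {
  opp <- mk_cluster(2010, strand = "-")
  stops_all_frames <- list(per_frame = c(3L, 2L, 4L), min_across_frames = 2L)
  ev <- locus_evidence(simple_gene,
                       opposite_strand_clusters = opp,
                       stop_profile_opposite = stops_all_frames,
                       evidence_extends = FALSE)
  d <- evaluate_locus(ev)
  expect_equal(d$node_path, c(1, 2, 3, 9, 10, 11, 12))
  expect_equal(d$endpoint, "negative_inconsistent")

  ev2 <- locus_evidence(simple_gene,
                        opposite_strand_clusters = opp,
                        stop_profile_opposite = stops_all_frames,
                        stranded_rnaseq_available = TRUE,
                        evidence_extends = FALSE)
  d2 <- evaluate_locus(ev2)
  expect_equal(d2$node_path, c(1, 2, 3, 9, 10, 13, 14, 15))
  expect_equal(d2$endpoint, "tentative_opposite_strand")
})

test_that("remaining endpoints are reachable from their evidence patterns", {
  ## DRS confirms the existing 3' end
  ev <- locus_evidence(simple_gene,
                       downstream_clusters = mk_cluster(3004),
                       bridges = list(mk_bridge()),
                       evidence_extends = FALSE)
  expect_equal(evaluate_locus(ev)$endpoint, "positive_structure_confirmed")

  ## no evidence at all
  ev2 <- locus_evidence(simple_gene)
  d2 <- evaluate_locus(ev2)
  expect_equal(d2$endpoint, "negative_insufficient")
  expect_match(d2$missing_layer, "evidence")

  ## unsupported structure with novel junctions and peaks: new model
  bad_junc <- structure(list(
    introns = data.frame(start = 1, end = 2, spanning_reads = 0,
                         verdict = "unsupported"),
    novel = data.frame(chrom = "chrS", donor = 1500, acceptor = 1800,
                       count = 9),
    structure_supported = FALSE), class = "junction_support")
  ev3 <- locus_evidence(simple_gene, downstream_clusters = mk_cluster(7200),
                        bridges = list(mk_bridge()), junctions = bad_junc,
                        evidence_extends = TRUE)
  expect_equal(evaluate_locus(ev3)$endpoint, "positive_novel_model")

  ## gapped-but-unbridged union coverage downgrades to tentative
  ev4 <- locus_evidence(simple_gene, downstream_clusters = mk_cluster(7200),
                        bridges = list(mk_bridge("gapped_but_bridged",
                                                 union_continuous = FALSE)),
                        evidence_extends = TRUE)
  expect_equal(evaluate_locus(ev4)$endpoint, "tentative_extension")

  ## spatially separated downstream expression: novel-feature route
  ev5 <- locus_evidence(simple_gene, downstream_clusters = mk_cluster(7200),
                        bridges = list(mk_bridge()),
                        separation_evidence = TRUE, evidence_extends = TRUE)
  d5 <- evaluate_locus(ev5)
  expect_equal(d5$endpoint, "tentative_novel_feature")
  expect_equal(d5$node_path, c(1, 2, 3, 4, 21))
})

test_that("decisions are deterministic", {
  ev <- locus_evidence(simple_gene, downstream_clusters = mk_cluster(7200),
                       bridges = list(mk_bridge()), evidence_extends = TRUE)
  d1 <- evaluate_locus(ev); d2 <- evaluate_locus(ev)
  expect_identical(d1$node_path, d2$node_path)
  expect_identical(d1$endpoint, d2$endpoint)
  expect_identical(d1$rationale, d2$rationale)
})

test_that("site selection applies the motif/priming rule table", {
  cl <- rbind(mk_cluster(4000, total = 90, motif = "canonical"),
              mk_cluster(3000, total = 50, motif = "none", priming = TRUE),
              mk_cluster(3500, total = 70, motif = "canonical",
                         priming = TRUE),
              mk_cluster(3800, total = 30, motif = "variant_ATTAAA"))
  got <- select_supported_sites(cl)
  expect_equal(got$accepted, c(TRUE, TRUE, TRUE, FALSE))
  ## accepted sites ranked by total count
  expect_equal(got$mode[got$accepted], c(4000, 3500, 3800))
  expect_match(got$note[got$mode == 3500], "retained with warning")
  expect_match(got$note[!got$accepted], "internal-priming")
})

test_that("all planted decoys are rejected in the noise-free limit", {
  scn <- get_scenario("ambiguous_multi_peak", seed = 2)
  res <- run_pipeline(scn)
  clusters <- res$clusters
  ranked <- select_supported_sites(clusters[clusters$strand == "+", ])
  expect_equal(sum(ranked$accepted), 1)
  expect_equal(ranked$mode[ranked$accepted], 4200)
  expect_true(all(ranked$mode[!ranked$accepted] %in% scn$truth$decoys))
})

test_that("downstream expression is classified by spatial separation", {
  gene <- gene_model("G", data.frame(role = "exon", chrom = "chrS",
                                     start = 1001, end = 2000, strand = "+"))
  cl <- mk_cluster(2600)
  d_sep <- numeric(3000); d_sep[1001:2000] <- 5; d_sep[2301:2900] <- 2
  rna_sep <- coverage_vector("chrS", 1, d_sep, source = "RNA-seq")
  expect_equal(classify_downstream_expression(gene, cl, rna_sep),
               "novel_feature_candidate")
  d_cont <- numeric(3000); d_cont[1001:2601] <- 5
  rna_cont <- coverage_vector("chrS", 1, d_cont, source = "RNA-seq")
  expect_equal(classify_downstream_expression(gene, cl, rna_cont),
               "utr_extension")
  expect_equal(classify_downstream_expression(gene, cl[0, ], rna_cont),
               "none")
})
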