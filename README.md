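# threeprime

Combined-evidence re-annotation of gene 3' ends and complex loci.

## The problem

Most reference annotations under-specify where transcripts actually end.
Strand-specific 3'-end sequencing (DRS-style single-molecule reads captured
at the poly(A) tail) locates cleavage-and-polyadenylation sites to within
about ±2 bp and identifies the transcribed strand, but cannot reveal gene
structure; RNA-seq reveals structure and extent but is un-stranded and
non-uniform; archival ESTs confirm transcripts but are sparse with
unreliable strand flags; sRNA-seq sees only short species. `threeprime` is
for annotators and transcriptomics analysts who want these data combined
into explicit, auditable per-locus re-annotation calls.

## What it computes

* **Poly(A) peak calling** — reads filtered to unique mappings with ≤ 3
  indels and length ≥ 25 nt; 3'-terminal bases counted per position; a
  position is retained only with ≥ 3 reads in *every* replicate and total
  Poisson signal-to-noise `n/√n ≥ 3` (so the minimum retained evidence is
  9 reads, S/N = 3); single-linkage clustering with a 25 bp gap, cluster
  mode at the highest-count position.
* **Sequence checks** — poly(A)-signal scan (AATAAA ≤ 1 mismatch, named
  variants ATTAAA/AATAAG, tandem AATAAATAAA) 10–40 bp upstream of each
  cleavage candidate; internal-priming detection from adenosine runs
  (≥ 6 A starting within 10 bp downstream, or A-fraction ≥ 0.7);
  per-frame stop-codon profiles; AT-richness.
* **Evidence bridging** — zero-coverage gap analysis (≥ 50 bp is
  significant), multi-source bridging verdicts
  (`continuous` / `gapped_but_bridged` / `unsupported`), terminus
  agreement within 10 bp, and exact-boundary splice-junction support.
* **Decision tree** — a deterministic eight-endpoint rule tree (3
  positive, 3 tentative, 2 negative endpoints) with a traced node path and
  concrete GFF3/TSV re-annotation proposals.
* **Small RNA** — miRNA 5p/3p arm-pair detection with dominant-arm calls,
  pri-miRNA delineation from flanking RNA-seq blocks, and un-paired
  short-feature (snoRNA-like) candidates.
* **Synthetic loci** — a seed-deterministic generator for nine locus
  classes with ground truth (±2 bp 3'-end jitter, Poisson replicate
  counts, planted motifs, priming decoys, coverage gaps, strand-flipped
  ESTs), used by the test suite and usable for benchmarking.

## Worked example

```r
library(threeprime)

scn <- generate_scenario("simple_extension", seed = 1)  # 4 planted sites
res <- run_pipeline(scn)
cat(report_locus(res), sep = "\n")
```

```
Locus report: GENE1 (chrS:1,001-3,000, + strand)
Endpoint: positive_extension (positive)
Decision path: 1 -> 2 -> 3 -> 4 -> 5 -> 6 -> 7 -> 8
Rationale:
  data_loaded                  TRUE
  structure_supported          TRUE
  downstream_peaks             TRUE
  spatially_separated          FALSE
  evidence_extends             TRUE
  terminates_at_strongest      TRUE
  continuous_coverage          TRUE
  no_sequence_contradiction    TRUE
Same-strand clusters downstream: 4
  mode 4,450  reads 22  snr 4.69  motif canonical  priming FALSE
  mode 4,900  reads 19  snr 4.36  motif canonical  priming FALSE
  mode 5,400  reads 23  snr 4.80  motif canonical  priming FALSE
  mode 7,200  reads 126  snr 11.22  motif canonical  priming FALSE
Proposed re-annotation: 4 alternative model(s), summary 6,198 bp
```

The four recovered clusters sit at the planted cleavage sites (jitter
never moves a mode by more than 2 bp), each carries a canonical AATAAA
signal 19 bp upstream and no internal-priming signature, RNA-seq/EST
coverage bridges the annotated gene end to the strongest (distal) cluster,
and the locus exits the tree at the positive-extension endpoint with one
alternative gene model per supported poly(A) site. The summary length
(6,198 bp) is the segment-sum of the proposed model ending at the distal
site, under the table convention `end − start` per segment.

A command-line wrapper with `simulate`, `callpeaks`, `annotate`, `report`
and `print-config` subcommands is installed at
`system.file("cli", "threeprime.R", package = "threeprime")`.

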