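---
title: "Combined-evidence re-annotation of 3' UTRs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined-evidence re-annotation of 3' UTRs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threeprime)
```

## The problem

Reference gene annotations are weakest at transcript 3' ends. Conventional
RNA-seq rarely pins down where a transcript is cleaved and polyadenylated,
EST archives are sparse and carry unreliable strand flags, and annotation
pipelines inherit both limitations. Strand-specific 3'-end sequencing
(DRS-style: single-molecule capture at the poly(A) tail) locates cleavage
sites to within about ±2 bp and identifies the transcribed strand
natively, but says nothing about gene structure and only probes the 3'
terminus. No single data type supports confident re-annotation; their
combination does. `threeprime` implements that combination as a reusable,
deterministic pipeline: peak calling on 3'-end tracks, sequence checks at
candidate cleavage sites, coverage bridging, small-RNA integration, and a
rule tree that turns the assembled evidence into one of eight endpoint
classes per locus.

## Coordinate and length conventions

All coordinates are 1-based and inclusive as displayed in annotation
tables; conversion to and from BED's 0-based half-open convention is
centralized in `to_bed_coords()` / `from_bed_coords()` so no other code
performs the shift. Minus-strand table rows given high-to-low are
normalized on ingest (`genome_interval()`), and the original display order
is retained for reports.

Published re-annotation tables report a segment "coverage" of
`end - start`, one less than the number of bases spanned. `paper_length()`
implements exactly this, because it reproduces every verified printed
per-segment value; `interval_span()` gives the base count. Summary rows in
those tables are the *sum of segment lengths*, which can differ from the
span of the summary interval by the number of internal segment boundaries
(e.g. a three-segment summary of 43,800 against a span of 43,802); one
published summary instead equals the span (719 vs a segment sum of 717).
`build_reannotation_record()` therefore stores both `summary_length_bp`
(segment sum, the table convention) and `span_bp`. Proposed segments must
abut; the canonical boundary offset is +1 (next start = previous end + 1),
but a 0 offset (shared boundary base) is tolerated because some printed
proposed rows use it.

## Peak calling on 3'-end tracks

`filter_reads()` applies the alignment-level rules: unique high-quality
mappings only, at most 3 indels ("fewer than four"), and read length of at
least 25 bases. The length comparison is inclusive (`>= 25`): of the two
phrasings used across the source datasets ("greater than 25" and "at least
25 bp") the inclusive one is adopted as the default, configurable via
`min_read_length`. Uniqueness for BAM-style records, which have no native
equivalent of the aligner's uniqueness flag, is defined as
primary/non-supplementary with mapping quality at or above `min_mapq`
(default 20).

`count_three_prime_ends()` places one count per read at its 3'-terminal
aligned base (highest coordinate for plus-strand reads, lowest for minus).
`replicate_position_filter()` retains a position only when it has at least
`min_reads_per_replicate` (default 3) reads in every replicate, and its
total Poisson signal-to-noise ratio `total / sqrt(total)` is at least
`snr_min` (default 3). At the default thresholds the minimum retained
evidence is therefore 9 reads with S/N exactly 3 — the printed "<= 3"
S/N constraint is read as a floor, since the surrounding requirement that
retained peaks be reproducible only makes sense that way. For
single-replicate datasets, `singleton_mode` drops count-1 positions only
and applies no S/N floor, mirroring how the single-replicate human dataset
was processed.

`cluster_peaks()` groups retained positions by single-linkage with a
maximum gap of `max_cluster_gap` (default 25 bp — between the ~20 bp broad
peaks and the 30 bp triple-peak groupings observed in real loci). The
cluster mode is the highest-count position; ties resolve to the most 3'
position in transcription direction, consistently favouring the distal
cleavage site. Subpeaks are counted as local maxima of the base-resolution
count profile, so member positions separated by uncovered bases are
distinct subpeaks and plateaus count once.

## Sequence checks at candidate sites

`scan_pas_motif()` searches the transcription-sense sequence upstream of a
candidate cleavage position for the canonical AATAAA hexamer with at most
one mismatch, plus the exact named variants ATTAAA and AATAAG and the
tandem 10-mer AATAAATAAA (reported as its own class). Distance is measured
from the motif's 3'-most base to the cleavage position. The scan window
defaults to 10–40 bp upstream, covering all offsets observed in the worked
loci (15–22, 17, 19, 24, 26) with margin; ties among equal-mismatch hits
resolve to the distance closest to 19 bp, the modal observed offset.
Whether mismatched forms of the named variants should also match is
undecidable from the source material; the package matches AATAAA ± 1
mismatch plus exact named variants, and documents this as an assumption.
Hexamers overlapping an N never match.

`assess_internal_priming()` flags a site when a run of at least
`priming_min_a_run` (default 6) adenosines starts within
`priming_window_down` (default 10) bases downstream, or when the A
fraction over that window reaches `priming_a_fraction` (default 0.7).
These thresholds encode "long runs of adenosine immediately downstream";
no numeric values are prescribed by the source, so they are documented
defaults, configurable in `pipeline_config()`.

`stop_codon_profile()` counts TAA/TAG/TGA per reading frame on a chosen
strand; the opposite-strand plausibility rule in the decision tree treats
"stops in every frame" (minimum across frames > 0) as evidence against a
single protein-coding gene on that strand. `at_fraction()` reports
(A+T)/(length − N).

## Bridging and junction support

`find_gaps()` reports maximal zero-depth runs of at least `min_gap_len`
bases (default 50, the threshold at which coverage gaps were treated as
significant). `bridge_region()` asks whether transcription evidence
connects an annotated 3' end to a candidate downstream cluster:

* `continuous` — at least one source alone covers the extension with no
  significant gap;
* `gapped_but_bridged` — no single source does, but the union of sources
  has no significant gap (each source's gaps are covered by another
  source), or union gaps remain but all are shorter than `unbridged_max`
  (default 500 bp) with at least half the extension covered;
* `unsupported` — otherwise.

EST strand flags are ignored for bridging and retained only for reporting,
because archival EST strandedness is unreliable — trusting it is exactly
what mis-annotates antisense loci. Un-stranded RNA-seq contributes to both
strands, which is why convergent-gene regions resolve only to tentative
endpoints (see below). The terminus agreement tolerance is 10 bp: evidence
observed to finish 1 bp beyond a cleavage cluster, plus the ±2 bp
positional accuracy of 3'-end reads, with margin. `junction_concordance()`
labels each annotated intron `supported` at `min_spanning_reads` (default
3; no threshold is prescribed, documented as an assumption) exact-boundary
spanning reads, `weak` below that, `unsupported` at zero, and reports
unmatched junctions as novel.

## The decision tree

`evaluate_locus()` deterministically traverses a fixed node tree and
records every visited node. Endpoints: three positive
(`positive_extension`, `positive_structure_confirmed`,
`positive_novel_model`), three tentative (`tentative_extension`,
`tentative_opposite_strand`, `tentative_novel_feature`), two negative
(`negative_insufficient`, `negative_inconsistent`).

The manual curation workflow this tree formalizes fixes the node
semantics only along two canonical traversals — a clean extension (nodes
1→8) and an opposite-strand locus (1,2,3,9,10,11,12 without stranded
RNA-seq; 1,2,3,9,10,13,14,15 with it). Those node numbers are preserved
verbatim.
The remaining terminals are a *reconstruction* and carry node ids 16–21:
insufficient evidence (16), extension with an unpinned terminus or
unbridged union gaps (17), alternative-structure check (18) leading to a
novel gene model (19), confirmation of the existing 3' end within the
terminus tolerance (20), and spatially separated downstream expression
routed to a novel-feature candidate (21). The predicates live in one
function so the mapping can be revised without touching callers.

Two reconstruction choices deserve note. First, node 6 ("continuous
coverage over the proposed extension, taken together") accepts both
`continuous` and `gapped_but_bridged` verdicts provided the union track is
gap-free — a multi-source bridge across single-source gaps is exactly the
situation the worked extension example presents. Second,
`select_supported_sites()` excludes priming-flagged clusters unless a
poly(A)-signal motif supports them (then retained with a warning note);
accepted clusters are ranked by total count and all become alternative
poly(A) sites in the proposal. The default downstream search extends
10 kb (one worked locus needed ~8.5 kb); `baseline_mode` restricts it to
300 bp, reproducing the blind spots of window-limited automated
re-annotation.

## Small-RNA integration

`detect_arm_pairs()` finds mature-miRNA 5p/3p arm pairs as two short sRNA
coverage peaks (footprint 18–25 bp) separated by a hairpin-loop-scale gap
(10–60 bp); the dominant arm is the higher peak unless the heights are
within a 1.25× ratio (then `balanced`). None of these bounds are
prescribed; they bracket the geometry of mature miRNAs and are
configurable. sRNA reads are un-stranded, so the locus strand is inherited
from DRS evidence. `delineate_pri_mirna()` models the primary transcript
as RNA-seq flanking blocks around zero-coverage hairpin-excision zones,
anchored 3' at the cleavage cluster downstream of the 3'-most arm.
`call_short_feature()` emits a snoRNA-like candidate when a single
un-paired sRNA peak coincides with a low-level RNA-seq block and at least
two weak cleavage clusters; arm-pair detection and short-feature calling
are mutually exclusive on a peak set.

## The synthetic-locus generator

`generate_scenario()` builds nine self-contained locus classes mirroring
the worked re-annotation examples: a clean multi-site extension, an
extension among internal-priming decoys, a curated two-site locus, a long
extension past the 300 bp baseline window, a wrong-strand annotation, a
convergent-gene region, completely overlapping antisense models, an
intergenic pri-miRNA, and a separated novel short feature.

The generative model encodes the study conditions: per-site read counts
are Poisson per replicate (three replicates by default); each read's 3'
end is jittered by a discrete triangular distribution on −2..+2 bp (the
stated accuracy bound gives only the support; the triangular shape
concentrates mass at the true site); background is Poisson at 0.02 reads
per base per replicate, chosen so the 3-reads-in-each-of-3-replicates
filter removes essentially all of it; RNA-seq depth uses lognormal
(sdlog 0.8) multipliers per 50 bp window; ESTs are sparse intervals whose
strand flag flips with probability 0.1. Zero-coverage gaps in RNA-seq are
*planted deterministically* (the clean-extension locus carries exactly
three sub-50 bp drops, each covered by an EST) rather than drawn from a
dropout process, so fixture truths are stable; stochastic dropout is the
real-data feature this sacrifices. Poly(A)-signal hexamers are planted at
known offsets inside scan windows that are otherwise scrubbed with an
adenosine-free pattern — necessary because an A-run is itself one mismatch
from AATAAA, so unscrubbed decoy windows would generate spurious motif
support (for the same reason priming decoys are spaced more than 50 bp
apart). Site depths (default mean 20 reads/site/replicate, the distal site
doubled; 15 for deliberately weak novel-feature sites) keep expected
decisions stable across Poisson draws at the per-position filter.

What passing these fixtures does *not* show: robustness to alignment
artifacts, base errors, low-complexity regions, or aligner-specific
uniqueness behaviour — alignments here are emulated at the count level,
not simulated at the read level.

## Numerical and interface choices

Identical inputs give byte-identical outputs everywhere: clustering and
tree traversal are deterministic, generation is seed-driven and restores
the caller's RNG state. Degenerate inputs are defined: empty tracks yield
empty (not failing) cluster sets; all-N intervals give `NA` AT fraction
with a warning; scan windows truncated at contig bounds warn and proceed.
The configuration round-trips through YAML (`read_config()` /
`write_config()`); YAML was chosen over an ini/TOML-style file because the
installed R stack parses it natively, and the file carries exactly the
`pipeline_config()` keys. The command-line entry point
(`inst/cli/threeprime.R`) is a thin wrapper over exported functions with
`simulate` / `callpeaks` / `annotate` / `report` / `print-config`
subcommands.

Problem sizes used by the shipped tests: contigs of 4–14 kb, 3 replicates,
up to 200 planted sites for the jitter-recovery property, 100 random 1 kb
sequences for the motif-scan oracle, and 1,000 random count triples for
filter monotonicity.

## Known limitations

* The decision tree beyond the two described traversals is a documented
  reconstruction; other reasonable node assignments exist.
* Internal-priming thresholds and arm-pair geometry bounds are package
  defaults, not values fixed by the source material.
* Overlapping and convergent loci resolve to tentative endpoints whenever
  un-stranded coverage is the only bridge — by design, since the strand
  ambiguity is real; stranded RNA-seq input is the cure.
* No transcript assembly or isoform quantification is attempted; the unit
  of work is one locus and its gene-associated regions.
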