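Package: threeprime
Title: Combined-Evidence Re-Annotation of 3' UTRs and Complex Loci
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-annotates gene 3' ends by combining strand-specific 3'-end
    sequencing (DRS-style poly(A) site peaks), un-stranded RNA-seq coverage
    and splice junctions, archival ESTs, and small-RNA data. Provides
    replicate-aware poly(A) peak calling with Poisson signal-to-noise
    filtering, poly(A)-signal motif and internal-priming sequence checks,
    coverage bridging between annotated gene ends and candidate cleavage
    clusters, miRNA 5p/3p arm detection, and a deterministic evidence-
    integration decision tree that classifies each locus into positive,
    tentative or negative re-annotation endpoints. A synthetic-locus
    generator emits fully specified test loci with ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
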