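Package: rnpchip
Title: ChIP-Seq Mapping of Intron RNP Binding Sites on Multi-Replicon
    Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates and characterizes group II intron ribonucleoprotein
    (RNP) binding sites on circular, multi-replicon bacterial genomes from
    ChIP-seq style read placements. Provides a windowed Poisson enrichment
    peak caller with local background estimation and Benjamini-Hochberg
    FDR control, construct-subtraction filtering of peak sets (bedtools
    intersect -v semantics), genomic-context and replication-fork
    leading/lagging-template annotation of peaks, origin-proximity
    statistics on circular replicons, GC-skew computation with
    changepoint-based ori/ter localization, scanning of sequencing
    libraries for 25-nt insertion-site occupancy, and input-vs-IP mean
    coverage comparison. A fully seeded synthetic-data generator emulates
    a tripartite rhizobial genome with planted binding sites, insertion
    sequence copies, GC-skew structure and replication-fork strand biases,
    providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    rlang,
    withr,
    stats,
    utils,
    methods
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
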