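Package: srnaqtl
Title: QTL Mapping of Small RNA Expression Traits in Immortalized F2
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genetic analysis of small RNA (sRNA) abundance in an
    immortalized F2 (IMF2) population. Provides a simulator for
    recombinant-inbred-line derived IMF2 populations with known sRNA
    QTL architecture; quantification of sRNA, sRNA-cluster and mRNA
    expression traits (RPM, median-of-ratios and FPKM scales);
    coverage-island sRNA cluster detection; genome scans by composite
    interval mapping on bin genotypes with permutation significance and
    FDR control; local/distant QTL classification; additive and
    dominance effect estimation with permutation dominance tests and
    overdominance calling; QTL hotspot detection; and co-regulation
    correlation analyses with simulation-based significance thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
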