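Package: chromod
Title: Domain-Architecture Discovery and Classification of Plant Histone
    Modifiers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide discovery and
    characterization of plant chromatin-modifier (histone modifier) gene
    families. Builds position-specific log-odds profiles from aligned
    domain blocks, calibrates detection thresholds against a background
    null and scans proteomes for domain hits; assembles per-protein
    domain architectures and classifies them into the HAT/HDAC/HMT/HDM
    superfamilies and their families and classes through an ordered rule
    engine with exclusion rules and a nearest-reference fallback;
    characterizes RPKM expression profiles (tiering, z-normalization,
    fruit-stage grouping, peak-stage and pseudogene calls); maps genes
    onto marker-delimited introgression-line bins and detects tandem
    duplication clusters; and ranks candidate genes by combining family
    membership, expression and bin phenotype keywords. Ships a
    transcribed 124-member tomato histone-modifier catalog with decoys,
    plus generators for fully synthetic benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, GenomeAnnotation, Classification, GeneExpression,
    Software
RoxygenNote: 7.3.3
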