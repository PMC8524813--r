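Package: satrep
Title: Enrichment of Broad Histone Marks at Annotated Satellite DNA Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying H3K9me3 (and other broad histone
    mark) enrichment at RepeatMasker-annotated satellite DNA instances from
    ChIP-seq signal tracks. Provides blocklist-aware instance selection,
    genome-median-normalized and clamped log2 fold-change enrichment over
    input, flanking-window profiles, differential enrichment between sample
    groups (Welch t-test) and across developmental stages (ANOVA, Bonferroni,
    Tukey HSD, fold-change relevance filter), satellite-family
    over-representation, sample-level multivariate structure (PCA, binomial
    dissimilarity, PERMANOVA), quantification of ambiguously mapped reads and
    consensus-dimer re-mapping enrichment for highly repetitive satellites,
    and overlap-based secondary analyses (peaks, RNA contigs, chromatin
    states, nucleosome occupancy, genes). A seeded synthetic-data generator
    emits a complete miniature dataset with ground truth so every stage is
    exercisable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    knitr
Config/testthat/edition: 3
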