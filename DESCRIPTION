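Package: clonediv
Title: Genetic Diversity and Mutation Dynamics in Clonal Fissiparous Planarian Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse genetic and phenotypic diversity in clonally
    propagated, fissiparous planarian lineages from multi-sample VCFs and
    individual-level reproduction logs. Implements the downstream site and
    genotype filters (depth band, pooled allele frequency, repeat masking,
    genotype-quality subsetting), substrain structure analyses (LD pruning,
    PCA, per-site and windowed Weir-Cockerham FST, windowed nucleotide
    diversity), runs-of-homozygosity detection with lineage-consensus and
    substrain-specific set algebra, somatic allele-frequency and allelic
    imbalance summaries, pedigree-aware detection of newly arisen mutations
    across consecutive head generations with false-negative calibration,
    transmission fractions and per-generation mutation-rate arithmetic, and
    reproduction-event analytics (waiting times, fission versus fragmentation,
    middle counts, death rates). A forward simulator of fission as a genetic
    bottleneck generates VCF, pedigree, reproduction-log and ground-truth
    outputs so every stage is verifiable on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
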