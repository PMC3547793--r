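Package: rilexpr
Title: Transcriptome Segregation Analysis for Intermated Recombinant Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of gene-expression segregation in intermated recombinant
    inbred line (RIL) populations such as the maize IBM (B73 x Mo17) panel.
    Provides empirical-FDR detection-threshold calibration from non-genic
    background, per-gene population statistics with a Gaussian-mixture
    bimodality score and paramutation-like pattern detection, composite
    interval eQTL mapping with permutation thresholds and 1-LOD support
    intervals, trans-eQTL hotspot discovery with haplotype-bias testing,
    presence/absence segregation typing with a block-adjusted two-locus
    epistasis scan, structural-variant and fragment co-expression association,
    and a forward simulator of intermated-RIL genotypes and expression with a
    fully known planted architecture for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
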