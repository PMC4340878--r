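Package: regulonscope
Title: Genome-Scale Transcription-Factor Regulon Analysis for Bacterial ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing a bacterial transcription-factor regulon
    from ChIP enrichment data: Poisson local-background peak calling with
    MACS-style -10log10(p) scores, strand-aware summit-to-gene annotation with
    operon expansion, ZOOPS expectation-maximization discovery of palindromic
    binding motifs, PWM scanning with exact score p-values, summit-motif
    geometry statistics, and feed-forward-loop logic classification of 2x2
    factorial expression designs. Includes a synthetic-data generator with
    recorded ground truth (high-GC circular genome, operon landscapes, planted
    binding sites, Poisson coverage, factorial qPCR-style expression) and the
    packaged NdgR binding-region and regulon tables for Streptomyces
    coelicolor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
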