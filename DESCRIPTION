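Package: mosaicDDPCR
Title: Quantification of Parental Mosaicism from Micro-Droplet Digital PCR
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of mutant allelic fractions (MAFs) from micro-droplet
    digital PCR (mDDPCR) droplet counts with exact binomial confidence
    intervals, correction for co-amplified homologous genomic regions, and
    mosaic calling at a configurable confidence-bound threshold. Includes a
    simplified beta-binomial posterior for amplicon deep-sequencing (PASM)
    MAF estimates, conditional-probability transmission statistics for
    paired sperm/blood measurements in mosaic fathers, exact cohort-level
    tests, hierarchical clustering of multi-tissue MAF profiles, a synthetic
    cohort and droplet-run generator with platform detection-limit
    benchmarking, and a packaged cohort of validated parental SCN1A mosaic
    mutations in a Dravet syndrome cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, ape
Suggests: testthat (>= 3.0.0), withr, VariantAnnotation, SummarizedExperiment,
    BiocGenerics, jsonlite, knitr
biocViews: Genetics, VariantDetection, ddPCR, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
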