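Package: rohscape
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands from SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window detection of runs of homozygosity (ROH) on
    SNP-array genotypes read from PLINK text files, computation of the
    genomic inbreeding coefficient F_ROH with its decomposition into recent
    and ancestral components by ROH length, and randomization-based
    detection of ROH islands (regions of population-wide homozygosity
    enrichment) with gene-interval annotation. Includes a synthetic
    population generator with planted homozygous tracts and shared islands
    for validating the whole pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
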