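Package: asecall
Title: Allele-Specific Expression and Methylation Calling from
    SNuPE/MALDI-TOF Peak Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative allele-specific expression (ASE) analytics for
    single-nucleotide primer extension (SNuPE) assays read out by MALDI-TOF
    mass spectrometry. Converts two-allele peak-intensity pairs into
    replicate-aggregated allelic fractions, corrects cDNA fractions by the
    matched genomic-DNA ratio to cancel assay-intrinsic allelic detection
    bias, validates assay accuracy against plasmid standard series, and
    calls ASE-positive samples in case/control cohorts with bidirectional
    Youden-index cutoffs and an alpha-outlier region on robust Huber
    M-estimates. Also analyses allele-specific DNA methylation (ASM) from
    bisulfite clone matrices split by a phasing SNP, normalizes
    mass-spectrometric methylation calls against mixing standards, and
    includes synthetic-data generators (binomial template-sampling noise,
    per-allele detection gain, planted-outlier cohorts, allele-specific
    clone populations, demethylation rebalancing) so the full pipeline is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
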