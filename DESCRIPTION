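Package: polyprof
Title: Genome-Wide Polysome Profiling Analysis of Bacterial Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sucrose-gradient polysome profiling of
    bacterial mRNA translation. Pools gradient subfractions into analysis
    fractions, normalizes per-fraction read counts (median-of-ratios size
    factors followed by ribodepletion-yield and total-RNA rescaling),
    computes per-gene mRNA fraction proportions, ribosome occupancy and
    ribosome density with bootstrap-on-residuals peak-fraction calling,
    compares translation profiles between low and high mRNA-concentration
    conditions, quantifies transcripts from spike-in normalized qPCR Ct
    values, and fits multiple linear regression models that rank gene
    covariates by their effect on translation. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), DESeq2, jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
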