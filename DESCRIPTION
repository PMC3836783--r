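Package: candseq
Title: Candidate-Gene Resequencing Fine-Mapping Analysis Chain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as tested and reusable functions, the complete
    computational chain of a candidate-gene resequencing fine-mapping study
    for a common complex disease: threshold-based SNP calling from pileup
    allele counts, variant annotation and discovery summaries, case-control
    quality control and allelic chi-square association, EM haplotype
    frequency estimation with confidence-interval LD blocks, an LD-aware
    simulation-based gene test, pairwise epistasis scanning, and a
    causal-variant consistency statistic (absolute logistic Z-scores
    regressed on the square root of r-squared with a candidate SNP).
    A synthetic-data generator emulates LD-structured case-control cohorts,
    sequencing pileups and missingness so that every stage is testable
    without access to controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    vcfR
Config/testthat/edition: 3
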