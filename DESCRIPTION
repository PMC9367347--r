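Package: cgassoc
Title: Candidate-Gene SNP Association Pipeline for Cattle Body Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for candidate-gene SNP association studies in
    livestock: in-silico PCR-RFLP genotyping (primer location, amplicon
    extraction, restriction digestion, gel band-pattern genotype calling),
    marker diversity statistics (gene heterozygosity He, effective allele
    number Ne, polymorphism information content PIC) with Hardy-Weinberg
    chi-square screening, fixed-effects linear-model association with
    Duncan multiple-range letter grouping at two significance levels, and
    relative gene-expression quantification by the 2^-ddCt method.  Ships
    the three KAT2B assays (g.T61908C, g.T62131C, g.C73406T) genotyped in
    four Chinese cattle breeds together with a synthetic-data generator
    that emulates the study design, so every stage is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
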