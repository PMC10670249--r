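Package: ringcyto
Title: Cytogenetic and Mutational Profiling of Ring-Chromosome Karyotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated cytogenetic and molecular analysis of
    hematological malignancies carrying ring chromosomes. Parses ISCN
    karyotype nomenclature into a structured clone/abnormality model,
    derives per-patient complexity and ring/marker features and cohort
    frequency tables, applies candidate-somatic variant filters and
    mutation-type classification, infers TP53 copy-number loss from
    chromosome-17 abnormalities and FISH signal patterns, and simulates
    seeded synthetic cohorts with a ground-truth ledger for pipeline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
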