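Package: cohortAF
Title: Cohort-Specific Allele Frequencies for Variant and Gene Prioritization in Rare Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a cohort-specific allele-frequency database from a
    heterogeneous rare-disease cohort sequenced with clinical exome panels,
    and uses it to boost diagnosis in a disease subcohort (inherited retinal
    dystrophies by default). Patients with unrelated diseases act as
    pseudocontrols. Provides identity-by-descent deduplication of samples,
    per-subcohort AF/AN/AC/homozygote tables with quality and
    population-bias filters, case-versus-pseudocontrol log2 fold-change
    prioritization of variants ("most frequent variants"), ACMG evidence
    recombination with injection of the PS4 criterion to reclassify variants
    of uncertain significance, per-gene deleterious-versus-benign Wilcoxon
    burden tests with false-discovery-rate control, and carrier-frequency
    estimation for recessive genes. A seeded synthetic-cohort generator
    emulates all required inputs so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
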