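Package: deepdnds
Title: Depth-Aware Selection Inference for Ultradeep Duplex Sequencing of Normal Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies somatic selection in polyclonal normal-tissue samples
    profiled by ultradeep duplex DNA sequencing. Implements a depth-aware
    dN/dS estimator on trinucleotide mutational-opportunity models (per gene,
    per consequence class, cohort-wide and per sample), selection on
    tumour-recurrent TERT-promoter mutations, frameshift-indel enrichment,
    single-site/residue/exon/domain selection scores, theoretical and observed
    kinetics of natural saturation mutagenesis, clone-fraction estimation from
    variant allele frequencies via inclusion-exclusion, and mixed-effects
    association of per-sample selection with donor covariates. Ships a
    synthetic cohort generator with known spectra, clone sizes and selection
    coefficients so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    seqinr,
    yaml
Config/testthat/edition: 3
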