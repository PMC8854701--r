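Package: endoclone
Title: Somatic Clonal Evolution Analysis of Normal Endometrial Glands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-gland somatic mutation data from
    normal tissue, built around single endometrial glands. Provides somatic
    call filtering and gland-level quality control, per-subject mutation
    burden and its association with clinical covariates, 96-class mutational
    spectra and reference-signature exposure fitting, trinucleotide-context
    Poisson dN/dS selection inference with driver-fraction estimates,
    VAF-based clone clustering with spatial grid mapping, neighbor-joining
    phylogenies of binary mutation profiles, a simplified allelic-imbalance
    caller for copy-neutral LOH, and molecular-clock timing of clonal
    expansions and CN-LOH events with resampling-based confidence intervals.
    A synthetic-cohort generator with full ground truth drives recovery tests
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    zoo,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    withr
Config/testthat/edition: 3
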