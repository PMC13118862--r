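Package: holo2brad
Title: Hologenome Profiling and Host Genotyping from Type IIB RAD Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for holobiont analysis from type IIB restriction
    site-associated DNA (2bRAD) sequencing. Builds a hologenome tag database
    from genome assemblies by in silico BcgI digestion, separating host-unique
    tags from microbial taxa-specific markers; filters and classifies
    sequencing reads against that database to profile microbial community
    composition (species presence and relative abundance) and to genotype the
    host at tag loci with codominant calls; and provides downstream community
    statistics (alpha diversity, Bray-Curtis, PERMANOVA), neighbor-joining
    trees, principal component analysis, replicate-concordance metrics, a
    metagenome-assembled-genome quality filter, and a synthetic holobiont
    data generator with complete truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
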