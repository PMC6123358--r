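Package: rumencult
Title: Culturomics Accounting of Rumen Microbiome Cultivability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dilution-to-extinction culturomics
    experiments on complex microbial communities such as the cow rumen.
    Provides OTU-table preprocessing (low-count filtering, seeded
    rarefaction, relative abundance, observed richness), set-theoretic
    cultivability accounting across media and dilutions (Venn partition,
    cultivable fraction, medium gain, rare-biosphere identification and
    cohort detection survey), a phylogenetic-cohesion permutation test on
    mean pairwise distances, Euclidean PCoA and two-way PERMANOVA, exact
    small-sample Wilcoxon tests with Holm-Bonferroni correction, a
    percentile-binned abundance-cultivability correlation, and a fully
    ground-truthed simulator of decimal dilution series plated in duplicate
    on two media alongside a multi-animal cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
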