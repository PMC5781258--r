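Package: coreshift
Title: Core Stress Microbiome Inference from Compositional OTU Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the belowground "core stress microbiome" from OTU count
    tables of plants exposed to multiple abiotic stresses (copper, drought,
    shade versus control). Provides rarefaction, filtered Shannon diversity,
    weighted UniFrac distances with PCoA, PERMANOVA and within/between-group
    permutation tests, per-treatment differential OTU calling with
    Benjamini-Hochberg control and cross-treatment direction-consistency
    tallies, a Gaussian naive Bayes treatment classifier with leave-one-out
    evaluation, compositionality-aware SparCC correlation networks with
    bootstrap pseudo-p-values, hub-subnetwork extraction and cross-treatment
    merging, and Pearson correlation linking of OTUs to metabolite or
    gene-expression features. A synthetic-data generator with a ground-truth
    record makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    biomformat,
    e1071,
    phyloseq,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
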