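Package: stratade
Title: Gender-Stratified Differential Expression Analysis of Microarray Studies
Version: 0.1.0
Authors@R:
    person("Stratade", "Maintainers", email = "maintainers@stratade.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for gender-stratified transcriptomic
    analysis of case/control microarray studies: SAM (Significance Analysis of
    Microarrays) permutation-based differential expression and per-gene
    multi-factor ANOVA over disease-by-gender contrasts, ANOVA-based batch
    removal with PCA quality control, probe-to-gene collapsing and merged
    multi-contrast fold-change matrices with overlap partitioning, one-sided
    Fisher exact gene-set over-representation with anchor-restricted
    comparative pattern extraction, gene-term association networks, composite
    key-gene classification, and 2^-DeltaCt qPCR relative quantification with
    cross-platform z-score concordance. Ships a synthetic-data generator that
    emulates a stratified nigral dopamine-neuron study design with planted
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, igraph, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
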