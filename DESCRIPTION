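Package: stentmb
Title: Microbiome Analysis of Biliary Stent Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of species-level (SGB) metagenomic profiles from
    biliary stents: sample retention filtering, alpha and beta diversity on
    arcsine-square-root transformed relative abundances with PERMANOVA and
    principal-coordinate ordination, prevalence/dominance summaries with body-site
    attribution, a two-level random-effects (DerSimonian-Laird) meta-analysis of
    disease associations on centered log-ratio transformed abundances, phylogenetic
    strain-sharing detection from normalized patristic distances, and antimicrobial
    resistance / biofilm gene-cluster assignment with pangenome-prevalence
    specificity classes. Includes synthetic-data generators emulating the
    statistical structure of stent cohorts, case-control panels, strain trees and
    gene-hit tables so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
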