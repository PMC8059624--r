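Package: traitvar
Title: Community-Weighted Trait Variance and Functional Diversity of
    Shifting Fish Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-trait community-weighted variance ("functional variance")
    analysis of community reorganization, alongside the classical taxonomic
    and functional diversity indices it is compared against. Implements
    trait-table ingestion with fuzzy coding, Gower distance over mixed trait
    types, UPGMA trait dendrograms and dendrogram-based functional richness,
    Shannon diversity and a regularized Pielou evenness, Rao's quadratic
    entropy, community-weighted mean and variance matrices with a PCA that
    yields functional variance PC1 scores and trait loadings, mixed-effect
    trend models of functional dispersion, and a synthetic two-region survey
    generator emulating boreal intrusion into an Arctic species pool.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    nlme,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'traitTable.R'
    'survey.R'
    'synthetic.R'
    'trends.R'
    'gower.R'
    'upgma.R'
    'diversity.R'
    'cwv.R'
    'pca.R'
    'pipeline.R'
    'cli.R'
    'utils.R'
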