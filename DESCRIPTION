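Package: otuassembly
Title: Community Assembly Analysis of Marine Protist OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing community assembly processes in marine protist
    (18S rRNA OTU) data sets sampled across seasons, habitats and depth layers.
    Provides OTU-table input/output with mothur '.shared' support, rarefaction
    and artifact filtering, classification of OTUs into six abundance/rarity
    categories, alpha-diversity estimators, rarefaction and species-accumulation
    curves, ordination (PCA, PCoA, NMDS, RDA) with Procrustes/PROTEST
    comparison, permutation inference (ANOSIM, Mantel, distance-decay), PCNM
    spatial eigenvectors, Sloan neutral-community-model fitting with parameter
    recovery diagnostics, thresholded Spearman co-occurrence networks with
    Storey q-value control and graph topology metrics, and a synthetic-data
    generator emulating a 60-sample coastal/shelf seasonal study design so
    every stage of the workflow can be validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    MASS
Config/testthat/edition: 3
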