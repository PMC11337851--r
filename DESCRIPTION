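Package: lrdmeta
Title: RNA:DNA Activity Index and Beta-Diversity for Oil-Dispersant
    Microcosm Metatranscriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Community-level analysis of paired metatranscriptomic and 16S
    rRNA gene count tables from oil/dispersant seawater microcosms:
    abundance-threshold aggregation of taxonomic labels to a fixed
    resolution, the log2 RNA:DNA (LRD) transcriptional activity index with
    its three-group classification, Bray-Curtis dissimilarity and principal
    coordinates ordination, abundance-weighted phylogenetic beta-diversity
    (mean pairwise and mean nearest taxon distances), and permutational
    multivariate ANOVA with sequential sums of squares over a factorial
    treatment-by-time design. Includes a Dirichlet-multinomial simulator of
    the microcosm design so the whole pipeline runs on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
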