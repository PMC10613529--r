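Package: microdivr
Title: Microdiversity, Persistence and Ecotype Analysis of Amplicon
    Sequence Variants within OTUs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying fine-scale (ASV-level) microdiversity
    inside 97%-identity OTUs in amplicon surveys of soil and rhizosphere
    microbial communities.  Implements de-novo OptiClust OTU clustering,
    rarefaction and alpha diversity, unweighted UniFrac ordination,
    permutation-based community statistics (ANOSIM, PERMANOVA, Mantel,
    Procrustes, SIMPER, Duncan multiple-range letters, Wilcoxon rank-sum),
    per-OTU microdiversity as the effective number of ASVs (exponential
    Shannon, a Hill number of order one), persistence and variability
    metrics, habitat-preference z-score profiles and ecotype-environment
    association, together with a seeded synthetic-community generator for
    validating every stage against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    picante,
    phangorn,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    biomformat
Config/testthat/edition: 3
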