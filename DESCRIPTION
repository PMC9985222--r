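Package: microcoalesce
Title: Differential Fitness Analysis of Microbial Removal and Coalescence Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-step soil microbiome manipulation
    experiments in which a community is depleted by removal treatments,
    allowed to recolonize sterile soil, and then coalesced with the
    untreated control community. Provides per-OTU Poisson generalized
    linear mixed models with read-sum offsets and observation-level
    random effects (adaptive Gauss-Hermite quadrature), a Laplace fit
    with kinship-correlated group effects for the coalescence step,
    Tukey-style single-step adjusted pairwise contrasts with a
    zero-abundance likelihood-ratio fallback, a set-algebra classifier
    of interaction and recovery categories, community-level diversity
    and weighted UniFrac / PERMANOVA recovery statistics, and synthetic
    data generators (parametric and mechanistic Ricker-type community
    dynamics) with planted interaction ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    phyloseq,
    picante,
    statmod,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
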