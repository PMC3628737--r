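Package: lipitax
Title: Integrated Analysis of Paired Gut Microbiota and Serum Lipidomics
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the joint analysis of paired gut-microbiota abundance
    profiles and serum lipidomics profiles from intervention cohorts.
    Implements profile-stability statistics (intra- and inter-individual
    Pearson correlations), empirical-Bayes moderated testing of intervention
    effects with an empirical permutation-based power calculation, a robust
    taxon-by-lipid correlation screen based on the biweight midcorrelation
    with Storey q-value false discovery rate control, constant plaid-model
    biclustering of the correlation matrix, structural-category enrichment of
    lipid species parsed from their shorthand nomenclature, and integration
    with enzymatically determined serum lipid panels.  A synthetic
    paired-cohort generator with a ground-truth ledger of planted effects and
    associations allows the whole pipeline to run and be validated without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
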