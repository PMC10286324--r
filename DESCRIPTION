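Package: FusionBurden
Title: Multi-Cohort Gene Fusion Characterization and Fusion-Burden Prognosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes gene-fusion call tables in the Arriba TSV dialect across
    RNA-seq cohorts of differing preservation types (fresh-frozen, FFPE) and
    library protocols, reproduces per-cohort fusion accounting and per-sample
    fusion burden, runs the discovery/confirmation cross-cohort candidate and
    novelty workflow against a known-fusion catalog, annotates fusion partners
    (gene class, snoRNA/host links, read-through candidates, partner
    promiscuity, gene-set enrichment), and associates dichotomized fusion
    burden with time-to-event outcomes via Kaplan-Meier estimation, log-rank
    tests and Cox proportional-hazards regression. A seeded synthetic-cohort
    generator emulates the statistical structure of such studies (known-fusion
    prevalences, negative-binomial background burden, FFPE degradation of call
    confidence with specimen age, linked Weibull survival) so the whole
    pipeline is testable without access to raw cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneFusionDetection, Survival, StructuralVariation
RoxygenNote: 7.3.3
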