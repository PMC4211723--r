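Package: hfcmig
Title: Heterozygosity-Fitness and Migration-Timing Genetics for Wild Cervids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype-phenotype analysis chain for microsatellite panels from
    wild deer populations: genotype ingest (CSV and GenePop dialects),
    single-population diversity statistics (multilocus and single-locus
    heterozygosity, exact Hardy-Weinberg tests, Weir-Cockerham F_IS, the g2
    identity-disequilibrium estimator), pairwise Queller-Goodnight
    relatedness, Mantel and partial Mantel permutation tests between
    relatedness and migration-timing distance matrices, Bayesian hierarchical
    regressions (negative binomial migration-timing, log-normal mass, beta
    body-fat models with random intercepts, DIC and shrinkage-prior refits),
    migration phenology extraction from GPS tracks via minimum convex
    polygons, and a seeded synthetic-data generator with known truth so the
    whole chain runs and is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    mgcv,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
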