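Package: foundertrace
Title: Founder-Effect Inference for Introduced Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs the introduction history of isolated populations
    founded by a small number of individuals. Provides mitochondrial and
    microsatellite diversity statistics (haplotype and nucleotide diversity,
    rarefied allelic and private allelic richness, heterozygosities,
    Weir-Cockerham inbreeding coefficients, exact Hardy-Weinberg tests),
    AMOVA-based Phi-ST and R-ST differentiation with permutation tests,
    isolation-by-distance tests on Vincenty geodesic distances,
    linkage-disequilibrium effective population size estimation with
    minor-allele-frequency screening and jackknife confidence intervals,
    Lincoln-Petersen mark-recapture census estimation, a female-founder
    mitochondrial haplotype retention simulation, an individual-based
    age-structured forward simulator of founding bottlenecks and drift under
    logistic growth with overlapping generations, grid-matching inference of
    founder size and annual growth rate, and a synthetic-data generator that
    emulates the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    geosphere,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
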