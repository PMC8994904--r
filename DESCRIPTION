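Package: ldepivar
Title: Genetic Variances Under Linkage Disequilibrium, Inbreeding and
    Digenic Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of quantitative-trait populations
    with controllable linkage disequilibrium (LD) under random mating or
    selfing, together with the matching variance-decomposition theory.
    Founder populations are built by crossing two linkage-equilibrium
    populations; digenic epistasis of the seven classic types
    (complementary 9:7, duplicate 15:1, dominant 12:3:1, recessive 9:3:4,
    dominant-and-recessive 13:3, duplicate-cumulative 9:6:1 and
    nonepistatic genic interaction 9:3:3:1) is imposed on pairs of genes
    with a user-controlled epistatic-variance magnitude.  Per generation
    the genotypic variance is partitioned into additive, dominance and
    four epistatic components plus all pairwise covariances, using the
    Kempthorne two-locus effects obtained by constrained weighted least
    squares generalized to LD and inbreeding, and validated against
    closed-form two-locus results (exact 10-state selfing recursion,
    LD decay under random mating, Cockerham's inbreeding components).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
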