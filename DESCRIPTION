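Package: pedgen
Title: Pedigree and Genomic Diversity Analysis for Livestock Populations
Version: 0.1.0
Authors@R:
    person("pedgen", "developers", email = "pedgen@example.org", role = c("aut", "cre"))
Description: Tools to assess genetic diversity in managed livestock
    populations from pedigree and medium-density SNP data. Implements
    pedigree inbreeding by the Meuwissen-Luo algorithm, average relatedness,
    pedigree-depth metrics (equivalent complete generations, completeness
    index), generation intervals by the four selection paths, probability of
    gene origin (effective numbers of founders and ancestors), realized
    effective population size from individual inbreeding rates, genomic
    inbreeding from Yang's genomic relationship matrix, sliding-window runs
    of homozygosity with FROH at genome, chromosome and length-class level,
    ROH-island selection-signature scanning, estimator correlations, and a
    gene-dropping simulator that supplies identity-by-descent ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
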