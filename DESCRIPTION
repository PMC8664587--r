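Package: pleiolink
Title: Forward Simulation and Multitrait Association Mapping of
    Pleiotropic Versus Linked Genetic Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based, forward-in-time Wright-Fisher simulation of
    two additive quantitative traits under Gaussian stabilizing and
    correlational viability selection, contrasting genetic architectures
    built from pleiotropic loci with architectures built from physically
    linked pairs of nonpleiotropic loci. Implements continuum-of-alleles
    and biallelic (QTN) mutation models, unidirectional migration between
    two demes, analytic mutation-selection-balance expectations for the
    G-matrix and the genetic correlation, population summary statistics
    (G-matrix, genic versus gametic covariance, multiallelic linkage
    disequilibrium r-squared, allelic kurtosis), and a downstream
    association-mapping stage: a centered genetic relatedness matrix,
    univariate regression scans, a multivariate linear mixed-model
    likelihood-ratio scan, Benjamini-Hochberg and Storey q-value
    correction, and truth-based discovery-rate scoring of true and
    spurious pleiotropy. PLINK .bed/.bim/.fam import and export is
    provided for interoperability with external association tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
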