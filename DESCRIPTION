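Package: basalClones
Type: Package
Title: Basal Cell Clonal Dynamics and Multi-Site Somatic Clone Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying clonal dynamics in mosaically labeled airway
    epithelium and in multi-site somatic sequencing data. Implements a lattice
    voter model of neutral and non-neutral (fitter-mutant) basal cell
    competition, identification of unlabeled "voids" and power-law analysis of
    their cumulative size distributions, Dirichlet-process mixture clustering
    of somatic variant allele fractions across microbiopsies by collapsed
    Gibbs sampling, pigeonhole-principle reconstruction of clone phylogenies
    with anatomical territory mapping, and ground-truthed synthetic data
    generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    optparse
biocViews: Software, CellBiology, Bayesian, Phylogenetics, SomaticVariants
Config/testthat/edition: 3
RoxygenNote: 7.3.3
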