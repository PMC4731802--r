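Package: allonet
Title: Dynamical Network Analysis of Correlated Motions in Biomolecular
    Ensembles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping allosteric communication in proteins and
    protein-DNA complexes from conformational ensembles. Implements
    mutual-information based generalized correlation coefficients
    (Kraskov k-nearest-neighbour estimator), per-residue correlation and
    residue-type contribution scores, contact-filtered weighted residue
    networks with shortest and sub-optimal communication pathways
    (Floyd-Warshall), Girvan-Newman community detection with a
    partition-convergence diagnostic, and essential-dynamics free-energy
    landscapes. Ships a synthetic elastic-network Gaussian ensemble
    generator with closed-form correlation oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    MASS,
    bio3d,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Network, PrincipalComponent
RoxygenNote: 7.3.3
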