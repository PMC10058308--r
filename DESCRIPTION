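Package: rpflex
Title: RNA Pocket Flexibility Analysis on NMR Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects binding pockets on every structural model of a
    multi-model (NMR) RNA deposition with a discrete two-probe grid
    method, clusters the pockets across models by voxel-overlap
    similarity, and quantifies each pocket group's conformational
    flexibility with a topology-aware score Q. The score is corroborated
    by nucleotide-averaged ensemble RMSF and by the cross-model
    variability of residue contact-network metrics (average degree,
    clustering coefficient, diameter, mean path length), and the
    hydrogen-bond and van der Waals contacts that rationalize rigidity
    versus flexibility are profiled by nucleotide chemical group and
    amino-acid category. Includes a deterministic synthetic-fixture
    generator (analytic voxel shapes, cavity-bearing atom shells,
    perturbed ensembles, toy graphs) so the whole pipeline is testable
    without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
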