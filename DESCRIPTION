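Package: filadyn
Title: Coarse-Grained Dynamics and Geometry of Enzyme Filamentation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural-dynamics toolkit for studying allosteric inactivation of
    enzymes upon filamentation, built around the bacteriophage T3 SAMase / E. coli
    methionine S-adenosyltransferase (MAT) heteropolymer system. Provides Go-model
    coarse-grained discrete molecular dynamics (event-driven square-well potentials
    on C-alpha beads) with a pocket-deformation statistic d_rms, Gaussian network
    model normal-mode analysis with per-mode inter-residue dynamic correlations
    (C_pocket, C_interface), PISA-style buried interface areas from Shrake-Rupley
    accessible surface areas, helical filament reconstruction by iterative
    replication of an asymmetric unit with screw-parameter and kink-angle
    extraction, and a seed-deterministic synthetic-structure generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, bio3d, Rcpp, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'filadyn-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'structio.R'
    'filament.R'
    'selection.R'
    'gnm.R'
    'godynamics.R'
    'interfaces.R'
    'synthetic.R'
    'pipeline.R'
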