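Package: pepscore
Title: Molecular-Dynamics Rescoring of Protein-Peptide Docking Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rescoring of coarse-grained protein-peptide docking decoys by
    receptor-ligand nonbonded interaction energy. Each all-atom complex model
    is refined by restrained steepest-descent minimization and short Langevin
    sampling with harmonic C-alpha restraints, scored by the time-averaged
    Coulomb plus Lennard-Jones interaction energy between receptor and
    peptide, and ranked. Includes the clustering-based baseline ranking
    (per-replica low-energy selection followed by k-medoids), ligand-RMSD
    evaluation against a reference structure, a receptor-substitution control
    experiment, and a synthetic decoy-set generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
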