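Package: postmd
Title: Post-Simulation Structural Analysis of Protein Complex Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for saved molecular-dynamics trajectories of
    protein complexes, oriented at enzyme-substrate dimer systems such as
    insulin-degrading enzyme entrapping amyloid-beta dimers. Reads and writes
    multi-model PDB trajectories; computes Kabsch-superposed RMSD time series
    and per-residue RMSF profiles; assigns three-state secondary structure
    (helix/strand/coil) from backbone hydrogen-bond geometry and summarises
    helix/strand percentages over analysis windows; builds residue-pair
    occurrence maps for hydrophobic, electrostatic and hydrogen-bond
    interactions and classifies region-pair contacts as strong, weak or none
    under a four-rule rubric; tracks named inter-residue distance and angle
    gauges of open versus closed conformational states; and estimates
    conformer populations and relative free energies from per-conformation
    energies by a Metropolis Monte Carlo walk with an exact Boltzmann oracle.
    Includes deterministic synthetic-data generators (ideal helices and
    sheets, two-chain dimer trajectories with prescribed contact occupancy,
    an open/closed toy assembly, Gaussian conformer energy ensembles) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
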