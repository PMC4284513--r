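Package: kvcoupling
Title: State-Dependent Protein-Lipid Salt Bridges, Nonbonded Energetics and
    Gating Analysis for Kv Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis machinery for dissecting voltage-sensor/pore coupling in
    voltage-gated potassium channels from molecular dynamics trajectories and
    voltage-clamp fluorometry recordings. Detects salt bridges between basic
    protein residues and PIP2 phosphate oxygens under periodic boundary
    conditions, estimates state-dependent contact probabilities with
    across-run error bars, classifies intrasubunit lipid binding sites, and
    decomposes the S4-S5/S6 nonbonded interaction energy per residue using
    CHARMM-style switched Lennard-Jones and Coulomb potentials with
    block-averaged errors. An electrophysiology layer provides fluorescence
    baseline correction (dF/F), bounded Boltzmann fits of F/V and G/V
    relations, apparent gating free energies and double-mutant-cycle coupling
    energies. Synthetic-data generators with known ground truth (toy
    membrane-protein trajectories with prescribed contact statistics,
    Boltzmann-shaped gating curves, drifting fluorescence traces) support
    property-based validation, and a deterministic pipeline driver runs all
    stages from one configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
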