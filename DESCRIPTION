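Package: cgkit
Title: Coarse-Grained Modeling and Analysis of Protein-Responsive Polypeptide Nanoassemblies
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Martini-style coarse-grained (CG) topologies for amphiphilic
    random copolypeptides (P1, composed of hydrophobic M1 and hydrophilic M2/M3
    monomers) and the carbocyanine dye DiI, applies the force-field
    modifications needed to model specific zinc-sulfonamide recognition by
    carbonic anhydrase (a Zn-ligand Lennard-Jones cross term, Zn coordination
    bonds, and protein-water interaction scaling), constructs simulation
    systems for self-assembly, cargo loading and protein-triggered disassembly
    with GROMACS-dialect coordinate, topology and run-parameter files, and
    analyses trajectories: DBSCAN aggregation clustering with a minimum
    bead-bead distance metric, cylindrical density profiles, gyration-tensor
    asphericity and prolateness, and Shrake-Rupley solvent-accessible surface
    area on CG beads. A synthetic-fixture generator emulates micelles,
    multicore aggregates, dispersed unimers, buried and exposed cargo, and
    stepwise disassembly so every analysis is testable without running
    molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
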