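Package: cepdock
Title: Protein-Ligand Docking with a Crossover Elitist Preservation Genetic Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small, self-contained protein-ligand docking engine built around a
    real-coded genetic algorithm with a crossover elitist preservation (CEP)
    mechanism and Lamarckian Solis-Wets local search. Ligand poses are encoded as
    translation + quaternion + torsion genomes over an AutoDock-style PDBQT
    torsion tree, scored with a semi-empirical pairwise energy model
    (12-6 van der Waals, 12-10 hydrogen bonding, screened electrostatics,
    Gaussian desolvation, torsional penalty), and judged by the standard
    heavy-atom RMSD < 2 Angstrom validity criterion. Includes a baseline GA for
    ablation, synthetic receptor-ligand fixtures with planted optima, analytic
    and lattice test landscapes with exhaustive oracles, and a benchmarking
    harness (repeated seeded runs, convergence traces, box statistics, one-sided
    rank-sum comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
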