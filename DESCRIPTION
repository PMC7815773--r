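Package: dockiface
Title: Native-Likeness Classification of Protein-Protein Docking Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates native-like from non-native-like protein-protein
    docking interfaces. Reads two-chain complexes in PDB format, scores decoy
    poses with CAPRI-style quality metrics (fraction of native contacts,
    interface RMSD via Kabsch superposition), extracts a fixed-schema vector
    of interface descriptors (per-residue-type accessible and buried surface
    area from a Shrake-Rupley engine, hydrogen bonds, salt bridges, an
    atomic-solvation-parameter estimate of the binding free energy, interface
    composition), categorizes decoys into native/non-native bands, assembles
    1:5 labeled training sets, and trains RBF-kernel support vector machines
    with Platt-calibrated probabilities evaluated by repeated 80/20
    cross-validation, ROC/AUC, and a probability-threshold sweep of confusion
    metrics. A seeded synthetic dimer and decoy-ladder generator makes the
    whole pipeline testable without external structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
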