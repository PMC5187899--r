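Package: pepscreen
Title: In Silico Proteolysis and Consensus Virtual Screening of
    Food-Derived ACE-Inhibitory Oligopeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in-silico discovery pipeline for anti-hypertensive
    (angiotensin-I converting enzyme inhibitory) oligopeptides from seed
    storage proteins. Simulates concurrent gastrointestinal proteolysis with
    PeptideCutter-style cleavage rules (pepsin, trypsin, chymotrypsin),
    builds deduplicated 2-6-residue oligopeptide libraries with peptide
    masses, matches them against a packaged bioactive-peptide reference,
    scores peptide conformers against sphere-based pharmacophore models with
    a normalized fit value, extracts typed receptor-ligand interaction
    fingerprints (hydrogen bond, hydrophobic, electrostatic, metal
    coordination) from PDB complexes, compares receptor structures by Kabsch
    superposition and TM-score, post-processes externally produced docking
    pose scores into multi-receptor consensus decisions with
    residue-frequency ranking, and recovers IC50 values from dose-response
    assays. A seeded synthetic-data generator provides ground-truth fixtures
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
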