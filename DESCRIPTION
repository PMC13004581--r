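Package: anionsense
Title: Anion-Sensing Fluorescent Protein Discovery and Trajectory Analytics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for discovering and mechanistically
    characterizing anion-sensitive fluorescent proteins. Mines family
    alignments for binding-pocket homologs, analyzes molecular-dynamics
    trajectories for anion entry, cavity residence, solvation shells and
    hydrogen bonding, summarizes constant-pH protonation records, and fits
    spectroscopic binding isotherms and chromophore pKa curves. Ships a
    synthetic-data module that generates every input with planted ground
    truth so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
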