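Package: loopscape
Title: Loop-Conformation Analysis for Glycoside Hydrolase Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of active-site loop flexibility in protein crystal
    structures, developed around the four loops (L1-L4) above the
    substrate-binding pocket of family-1 beta-glucosidases. Provides
    region-restricted Kabsch superposition with iterative outlier rejection,
    per-residue C-alpha displacement profiles, normalized (z-score) B-factor
    flexibility profiles, geometric hydrogen-bond and hydrophobic contact
    detection, folded-versus-straight loop-conformer classification,
    pocket-entrance geometry and formal-charge annotation, pairwise global
    sequence alignment for loop-region comparison across homologs, and a
    seeded synthetic-structure generator with full ground truth for testing
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
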