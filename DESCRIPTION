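Package: patrep
Title: Pattern-Based Drug Repurposing from Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines maximal amino-acid substring patterns shared by a
    configurable fraction of a drug-target protein set, locates those
    patterns in disease protein sets, scores protein-pair similarity with
    four customized normalized Needleman-Wunsch schemes (identity weights,
    two physicochemical classifications, and BLOSUM62), compares similarity
    distributions with Lilliefors and Mann-Whitney U tests, and emits
    (target protein - drug - new protein) repurposing triplets filtered by
    similarity bands. Includes a seeded synthetic-data generator with
    planted motifs so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nortest,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
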