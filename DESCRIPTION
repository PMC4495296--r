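Package: structvar
Title: Annotation of Coding Variants on 3D Structures of Proteins and Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Maps single-amino-acid variants onto 3D structures of proteins and
    binary protein-protein complexes, reconciles isoform and structure sequences
    with Smith-Waterman local alignment, extracts residues in spatial contact
    (default 5 Angstrom minimum heavy-atom distance) including interface
    residues of the partner chain, joins direct and contacted positions against
    functional feature, somatic mutation and damage-prediction tables, and
    produces per-variant reports with rule-based damaging calls and
    confusion-matrix evaluation metrics. Includes deterministic synthetic
    fixture generators so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
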