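Package: pairdex
Title: Detection, Protonation Typing and Canonical Naming of Nucleobase
    Homo-Pairs in Small-Molecule Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Locates nucleobase moieties (adenine, guanine, hypoxanthine,
    thymine, uracil, cytosine and their glycosidic derivatives) in
    small-molecule crystal structures, detects planar, doubly
    hydrogen-bonded homo-base pairs using van der Waals distance, ring-plane
    and donor-hydrogen-acceptor angle criteria, classifies protonation
    patterns and formal charges, and assigns canonical atom-level pair names
    compatible with the Leontis-Westhof edge nomenclature.  Includes a
    synthetic fixture generator covering the full catalogue of observed
    homo-pair types, crystallographic symmetry expansion for contact
    searches, and survey statistics (refcode-family deduplication, frequency
    and protonation cross-tables, hydrogen-bond geometry summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
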