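Package: morphokey
Title: Morphological Diagnostics and Dichotomous Keys for the Schistura
    cincticauda Species Group
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for taxonomic diagnosability analysis of multistate and
    meristic morphological characters: a character-matrix model with
    qualitative state sets, integer count ranges and two-lobe fin-ray
    formulas; an interpreter, verifier and greedy generator for dichotomous
    identification keys; exhaustive minimal-diagnostic-set discovery;
    specimen classification with conflict reporting; and unordered
    (Fitch/Hartigan) parsimony mapping of coded characters on rooted trees
    with synapomorphy and homoplasy reports. Ships the character comparison
    table, morphocode scheme, printed identification key and specimen panels
    of the Schistura cincticauda species-group revision as validated
    fixtures, plus seeded generators for synthetic matrices, specimens and
    trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
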