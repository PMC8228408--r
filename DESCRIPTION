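Package: rnaccretion
Title: RNA Accretion History, Ordered-Character Parsimony and the
    Menzerath-Altmann Law
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the evolutionary accretion history of RNA
    molecules from their secondary structures. Secondary structures
    (dot-bracket, CT, bpseq) are decomposed into homologous substructures
    (stems, loops, bulges, joints, free ends) whose lengths are coded as
    ordered (Wagner) multistate characters in alphanumeric NEXUS matrices.
    Character-state changes are traced along rooted trees under generalized
    (Sankoff) parsimony and aggregated into step-matrices of unambiguous
    ancestral-to-descendant changes (bubble-chart data). Relative ages of
    substructures are derived from rooted trees of substructures as node
    distances, and the dependence of substructure length on age and on the
    number of accumulated parts is tested with correlation statistics and
    fitted with the special and general forms of the Menzerath-Altmann law.
    A synthetic-data generator produces accretion histories, stepwise
    character evolution and molecule sets with known ground truth, so every
    stage of the pipeline can be validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    minpack.lm,
    nortest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
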