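Package: metscreen
Title: Substrate Discovery Screens for Uncharacterized SET/PR-Domain
    Methyltransferases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Candidate-substrate screening toolkit for SET/PR-domain lysine
    methyltransferases with poorly characterized activity. Generates
    lysine-centered heptapeptide repertoires from protein sequences, filters
    ensembles of enzyme-peptide-cofactor structural models by SN2
    methyl-transfer and proton-transfer active-site geometry criteria, scores
    peptide binding with a simplified linear-response-approximation (LRA)
    screened-Coulomb electrostatic model, profiles catalytic tyrosine
    conservation to predict methylation capacity, and screens gene
    dependency or expression matrices for co-dependent partners by Pearson
    correlation. Includes synthetic-data generators with known ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
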