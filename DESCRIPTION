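Package: emtscreen
Title: Mesenchymal-Score Profiling of Candidate EMT Mediators in Bulk Tumor Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens bulk tumor expression for candidate epithelial-mesenchymal
    transition (EMT) mediator genes by combining three observable layers: the
    stroma-to-epithelium log2 fold change from paired micro-dissected tissue,
    a per-gene "mesenchymal score" (the correlation between a gene's genome-wide
    bulk co-expression profile and that fold-change vector), and a per-gene
    univariable Cox proportional-hazards z-score of prognosis. Candidate EMT
    mediators are genes that look epithelial in pure tissue yet co-express with
    the stromal program in bulk tumors and carry adverse prognostic weight.
    Includes survival, contingency-table, and clustering statistics used for
    clinical validation of such candidates, and a synthetic-cohort generator
    with known ground truth for end-to-end testing of the screen.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
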