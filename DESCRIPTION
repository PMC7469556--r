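Package: adipolink
Title: Linking Monogenic Lipodystrophy Genes to Case-Control Adipose
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline connecting a monogenic disease gene set
    (lipodystrophy genes) to case-control adipose-tissue expression profiles:
    non-specific filtering and empirical-Bayes moderated-t differential
    expression, disease-gene interactome construction and overlap with
    differentially expressed genes, dual-centrality (degree and bottleneck)
    hub prioritization, hypergeometric over-representation analysis,
    weighted co-expression modules with eigengene-trait correlation run
    separately per group, and per-patient flagging of disease genes that
    deviate beyond a control-derived envelope. Includes a seeded synthetic
    cohort generator with a full truth record so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
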