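Package: readerstudy
Title: Consensus-Based Analysis of Multi-Reader Diagnostic Accuracy Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-reader multi-case (MRMC) diagnostic accuracy
    studies in which several imperfect observers (e.g. radiologists and an AI
    system) each label radiographic findings as normal or abnormal and no
    external reference standard exists. Ground truth is proxied by the
    consensus (majority) label across all observers of a finding; per-observer
    accuracy, sensitivity and specificity are micro-averaged over pooled
    outcome counts; findings are stratified by inter-observer assessment
    variance into unanimous, low-ambiguity and high-ambiguity subsets; and
    observers are compared with two-proportion z-tests under Bonferroni
    correction, including a probabilistic-guessing benchmark. A synthetic
    reader-panel generator with latent truth, heterogeneous observer operating
    points and per-finding difficulty makes every stage testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
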