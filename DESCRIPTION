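Package: cotox
Title: Co-Toxicity Analysis of Binary Pesticide Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the joint toxicity of binary pesticide
    mixtures from dose-mortality bioassays. Provides Abbott's control
    correction, linear log-dose and probit dose-response fitting with LC50
    estimation and bootstrap confidence intervals, the co-toxicity
    coefficient (CTC) with synergism/cumulative/antagonism classification,
    serial-dilution and mixture-ratio experimental design helpers,
    fungicide-compatibility metrics (mycelial growth inhibition and spore
    germination), and a synthetic bioassay simulator with known ground
    truth for method validation. Includes a command-line interface for
    batch analysis of bioassay tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
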