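Package: disablife
Title: Multistate Life Tables for Compression of Disability in Biennial Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age-specific annual probabilities of disability onset,
    remission, and mortality from biennial longitudinal panel data (Health and
    Retirement Study style), with inverse-probability weighting for wave
    nonresponse, and feeds them into a five-state discrete-time Markov cohort
    model over ages 50-70 to summarize disability-free years, disabled years,
    life-years lost, and average age of disability onset, with Monte Carlo
    interval estimation. Includes a synthetic-panel generator with known
    ground-truth transition dynamics so the whole pipeline is testable without
    access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
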