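Package: rbcflow
Title: Stock-and-Flow Simulation of the Red Blood Cell Supply with
    Age-Threshold Issuing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo stock-and-flow simulation of a national red blood
    cell (RBC) supply chain with an aggregate collector bank and an aggregate
    hospital bank. Implements age-based issuing policies (FIFO, LIFO,
    oldest-first, newest-first) and a three-stage Threshold Method that
    preferentially transfuses fresher units to high-risk patient groups
    (exact ABO/Rh match within the age threshold, then compatible units
    within the threshold, then a freshest-available fallback), with ABO/Rh
    compatibility matrices, Dirichlet-multinomial phenotype-prevalence
    uncertainty, steady-state initialization, common-random-number replicate
    experiments, and supply/expiry/unmet-by-age performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
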