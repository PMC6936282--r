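Package: denitkin
Title: Growth Kinetics and Partial-Denitrification Performance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the growth kinetics of partial-denitrifying
    bacteria. Implements the Andrews (Haldane), Aiba and Edwards
    substrate-inhibition growth laws and their interactive double-substrate
    extension, bounded multi-start nonlinear least-squares parameter
    estimation with R-squared model ranking, Arrhenius temperature
    dependence of the maximum specific growth rate, batch-culture
    denitrification performance metrics (nitrite accumulation and nitrate
    removal efficiencies, specific degradation rates, log-phase growth
    rate), and relative gene expression by the 2^-ddCt method. A seeded
    synthetic-data module generates growth-rate tables, batch time series
    and qPCR Ct tables with known ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
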