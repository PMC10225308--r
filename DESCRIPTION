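Package: dopacca
Title: Dopamine Receptor Availability and Risky Investment Behavior:
    Simulation and Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying multivariate brain-behavior association in a
    learning-based risky investment task. Simulates the stock-versus-bond task
    with an objective Bayesian belief oracle, generates synthetic adult cohorts
    with age-linked regional dopamine D2-like receptor availability (binding
    potential), computes five behavioral error measures (choice inflexibility,
    first stock choice, suboptimal investment, absolute estimation error,
    optimism), and relates the two variable sets with a from-scratch canonical
    correlation analysis including sequential Wilks-lambda/Rao-F dimension
    reduction tests, standardized and structure coefficients, and univariate
    follow-up regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
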