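Package: feedAUC
Title: Feeding-Pattern Phenotyping and Pedigree-Based Genetic Analysis
    for Automated Feeder Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives within-day feeding-pattern phenotypes for lactating
    dairy cows from visit-level automated-feeder event logs: the area
    under the curve (AUC) of daily cumulative feed-intake proportions,
    anchored at the time of first fresh-feed delivery, and its
    day-to-day consistency (natural log of the variance of daily AUC).
    Also derives feed-efficiency traits (dry matter intake, secreted
    milk energy, metabolic body weight, body-weight change and residual
    feed intake) and estimates heritabilities and genetic correlations
    with a Bayesian pedigree animal model fitted by Gibbs sampling,
    including Henderson-rule construction of the inverse numerator
    relationship matrix with inbreeding, highest-posterior-density
    summaries and MCMC convergence diagnostics. A synthetic-data
    generator emulates feeder event streams, pedigrees, breeding values
    and efficiency records so the full pipeline is testable without
    proprietary station data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
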