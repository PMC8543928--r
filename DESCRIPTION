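Package: bae
Title: Bayesian Additional Evidence Tipping-Point Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse-Bayes sensitivity analysis for single effect estimates.
    Given a normally distributed effect estimate and its uncertainty (a hazard
    ratio, odds ratio, risk ratio or raw coefficient with a confidence
    interval, p-value or standard error), computes the Bayesian Additional
    Evidence tipping point: the least extreme hypothetical replication result
    that, used as a prior in a normal-normal conjugate update, makes a
    non-significant result posterior-credible, or a significant result
    non-credible. Includes forward posterior updating with credible intervals,
    prior-precision scaling for hypothetical larger studies, reference-prior
    credibility checks, summary-level simulation utilities, and a command-line
    interface producing human- and machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
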