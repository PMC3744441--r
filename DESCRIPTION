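Package: tadar
Title: Transmission and De Novo Association Tests for Rare Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level association testing for rare, dominant-acting
    variants that integrates de novo mutation counts from family trios,
    transmitted and nontransmitted inherited variants, and case-control
    carrier counts in a single hierarchical Bayes model (the TADA
    framework). Per-gene evidence is summarized as a Bayes factor that
    contrasts a risk-gene model, in which the relative risk and allele
    frequency carry Gamma priors, against a null model; prior
    hyperparameters are estimated by empirical Bayes across the exome,
    and significance is assessed against a simulated genome-wide null
    distribution with Benjamini-Hochberg false-discovery control.
    Also provides the simpler comparison tests (recurrence/multiplicity,
    Poisson de novo test, Fisher-combined meta test), estimators of
    genetic architecture (number of risk genes and mean relative risk
    from de novo enrichment and multi-hit counts), and a genome-wide
    simulator for power and false-discovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
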