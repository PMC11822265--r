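Package: irctcea
Title: Markov Microsimulation Cost-Utility Analysis of Surgery for
    Irreparable Rotator Cuff Tears
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic Markov microsimulation comparing the cost-utility
    of four surgical strategies for massive irreparable rotator cuff tears:
    superior capsular reconstruction (SCR), lower trapezius tendon transfer
    (LTTT), subacromial balloon spacer (SABS) and reverse shoulder
    arthroplasty (RSA). Builds probabilistic sensitivity analysis (PSA)
    input distributions by method of moments (gamma for costs, beta for
    transition probabilities, normal for utilities), simulates individual
    patients through an annual-cycle state-transition model with discounted
    cost and QALY accrual, and aggregates iterations into standard
    cost-effectiveness statistics: ICERs with absolute and extended
    dominance, net monetary benefit, cost-effectiveness acceptability
    curves, optimal-strategy shares and confidence ellipses on the
    incremental cost-effectiveness plane. Includes exact deterministic
    oracles (cohort expectation and exhaustive trajectory enumeration) and
    a synthetic-scenario generator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
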