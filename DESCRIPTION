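Package: premnet
Title: Permuted Relational Event Models for Dynamic Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing dynamic partner choice in animal social
    networks with permuted Relational Event Models (pREMs). Observed dyadic
    association events are paired with "non-events" generated by constrained
    data-stream permutations (within day-by-location subsets, with loop
    removal by re-shuffling and constrained label swaps), time-varying
    network covariates are computed from the event history, and the
    stratified Cox partial likelihood -- which for the 1:1 event/non-event
    design reduces exactly to a matched conditional-logistic likelihood --
    is maximised per permuted replicate. Coefficient distributions across
    replicates yield median incidence rate ratios, quantile confidence
    intervals and significance calls. Also included: an agent-based
    simulator of a dual-feeder "biological market" foraging experiment with
    a four-state reward task and tunable class-learning and
    affiliate-retention parameters, extraction of ordered association
    events from RFID perch-visit streams, non-model permutation tests
    (success-proportion null intervals, cumulative success/fail
    differential envelopes), and closed-form null expectations for dyad and
    triad class composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival
Config/testthat/edition: 3
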