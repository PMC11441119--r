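Package: allocbias
Title: Impact of Allocation Bias on Error Rates in Multi-Endpoint Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the impact of third-order allocation bias on test
    decisions in randomized two-arm parallel-group clinical trials with
    multiple continuous endpoints. Implements seven restricted and
    unrestricted randomization procedures (complete randomization, Efron's
    biased coin, big stick design, Chen's design, the maximal procedure,
    random allocation rule and permuted block randomization), the
    convergence-strategy biasing policy with endpoint-specific bias effects,
    the cumulative distribution function of the doubly non-central
    t-distribution, and closed-form per-list error rates: the family-wise
    error rate of the Sidak procedure for multiple primary endpoints
    (including a principal-component path for correlated endpoints) and the
    type I error rate of the all-or-none (intersection-union) procedure for
    co-primary endpoints. A Monte-Carlo driver evaluates randomization
    procedures over large samples of randomization lists, summarising mean
    error rates and the probability that the nominal level is maintained, as
    an aid to choosing a randomization procedure at the design stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
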