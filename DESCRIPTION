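Package: msmclock
Title: Multi-State Event-History Analysis with Deterministic Clock Transitions
    and Dynamic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clock-forward Markov multi-state analysis of
    event-history data with treatment-schedule states that change at fixed
    clock times, as arise in adjuvant chemotherapy trials. Provides a
    declarative state-space definition with deterministic transition rules,
    conversion of patient records to stacked long-format transition data
    (including midpoint imputation of interval-coarsened times and a
    direct-transition rule for event-triggered treatment discontinuation),
    transition-specific Cox proportional-hazards fits with an event-count
    gate, covariate-specific Aalen-Johansen transition probabilities by
    product integration with forced jumps at the scheduled times,
    fixed-horizon dynamic prediction of survival along evolving clinical
    histories, bootstrap standard errors, and a clock-forward Markov
    simulator that emulates the data limitations of such trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
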