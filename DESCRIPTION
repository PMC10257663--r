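Package: lctcycle
Title: Linear Chain Trick Models of Cell-Cycle Phase-Specific Drug Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mean-field linear-chain-trick (LCT) models of drug-modulated
    progression through the G1 and S-G2 cell-cycle phases, with Erlang-distributed
    phase durations, phase-part-specific death rates, and Hill dose-response
    parameterization. Includes a stochastic single-cell branching-process
    simulator whose expectation is the mean-field system, preprocessing of
    population time courses (normalization, Savitzky-Golay smoothing, replicate
    averaging), simultaneous differential-evolution fitting across drugs and
    doses with local sensitivity analysis, gamma-shape estimation from
    single-cell phase durations, and Bliss-independence prediction of two-drug
    combination responses on cell-cycle rates and on cell numbers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    MASS,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
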