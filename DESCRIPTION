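Package: tolcat
Title: Tower of London Adaptive Testing Engine and IRT Calibration
Version: 0.1.0
Authors@R:
    person("tolcat", "developers", email = "tolcat@example.org", role = c("aut", "cre"))
Description: Headless engine for the Tower of London (TOL) computerized
    adaptive planning test. Provides exact state-space construction and
    optimal (minimal-move) solving for capacity-limited peg boards and for
    the Tower of Hanoi, parameterized item-bank generation with move- and
    time-limit schemes, a three-phase adaptive administration procedure
    (familiarization, assessment, testing) with millisecond event scoring,
    dichotomous item-response-theory calibration (Rasch, 2PL, 3PL) by
    marginal maximum likelihood EM with Gauss-Hermite quadrature, item and
    test information functions, chi-square item fit, AIC/BIC/likelihood-ratio
    model comparison, and simulation tools for synthetic respondents and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
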