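Package: renoscale
Title: Single-Species Rat-to-Human Extrapolation and PBPK Simulation of
    Tofacitinib in Renal Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to predict human tofacitinib pharmacokinetics under
    normal renal function and moderate or severe renal failure from rat
    data alone.  Provides non-compartmental analysis of plasma
    concentration-time profiles, species-invariant (Dedrick) time
    projection of rat profiles to humans, single-species extrapolation of
    total and renal clearance with unbound-fraction and renal-blood-flow
    corrections, a whole-body perfusion-limited physiologically based
    pharmacokinetic (PBPK) model with Rodgers-Rowland tissue partitioning,
    a synthetic rat-profile generator anchored to published
    renal-failure rat pharmacokinetics, and validation statistics
    (R ratio, two-fold acceptance band, f1 difference factor) against
    observed clinical values.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
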