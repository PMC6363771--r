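Package: avctrl
Title: Model-Based Design of Minimum-Fuel Drug Schedules for Autophagy Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing drug dosing schedules that drive and hold the
    autophagic vesicle (AV) count of a cell at a target level. Implements a
    nonlinear ODE model of the kinase network regulating AV synthesis (MTORC1,
    ULK1, AMPK, VPS34) with Hill-function regulation and idealized first-order
    drug pharmacokinetics; simulation-based characterization of long-time
    behavior (phase diagrams, oscillation envelopes, dose-response curves,
    EC50 estimation); and a minimum-fuel optimal-control solver based on
    Legendre-Gauss-Lobatto pseudo-spectral collocation with an augmented
    Lagrangian nonlinear-programming backend, including feasibility validation
    by independent re-integration and first-order optimality diagnostics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
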