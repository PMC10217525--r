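Package: thermogate
Title: Stochastic Thermodynamics of Tension-Gated Ion Channel Erasure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Landauer-style bit erasure in a two-state
    mechanosensitive ion channel (MscS-like) driven by piecewise-linear
    membrane tension protocols. Provides an exact (inversion-sampling)
    stochastic simulator for tension-dependent Arrhenius gating kinetics,
    trajectory-level work/heat/entropy bookkeeping with first-law checks,
    a synthetic patch-clamp current trace generator, a single-channel
    step (edge) detector, and an orchestration layer that reproduces the
    convergence of the mean dissipated heat to the Landauer bound
    kB*T*ln(2) under quasi-static driving.
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
    withr
Config/testthat/edition: 3
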