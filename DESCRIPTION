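Package: wheatgdt
Title: Organ-Level Wheat Growth Simulator with Explicit Growth-Defense Trade-Offs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time, organ-level simulator of carbon and nitrogen
    budgets in a wheat plant. Leaf gas exchange follows the
    Farquhar-von Caemmerer-Berry biochemical model coupled to
    Ball-Woodrow-Berry stomatal conductance with Arrhenius temperature
    scaling; root nitrate uptake combines high- and low-affinity transport
    systems regulated by root carbon status. Organs emit local stress
    signals that drive dynamic defense coefficients (dose-response with
    induction/relaxation hysteresis), an explicit defense sink competing
    with growth, and defense-augmented maintenance respiration. Allocation
    from a common labile pool is hierarchical (maintenance first, then
    defense, then growth) under stoichiometric C:N constraints, so that
    growth-defense trade-offs under single and combined abiotic-biotic
    stresses can be simulated, audited for mass balance, and analysed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
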