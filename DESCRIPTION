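Package: caaPBPK
Title: Physiologically Based Pharmacokinetic Model for 3-Chloroallyl
    Alcohol in the Rat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Flow-limited physiologically based pharmacokinetic (PBPK)
    model for oral dosing of 3-chloroallyl alcohol (3-CAA) in the rat,
    with saturable hepatic metabolism parameterized by molecular-weight
    read-across from ethanol.  Simulates oral gavage and drinking-water
    dosing regimens as square-pulse infusions into a gut compartment,
    computes the dose metrics used in study design (venous Cmax, AUC,
    systemic bioavailability, bone-marrow exposure), and reproduces
    route-comparison scans across a grid of metabolic capacity (VmaxC)
    and affinity (Km) values.  The differential equations are integrated
    with deSolve using a compiled right-hand side, with integration
    restarted at every infusion pulse edge so that delivered mass is
    exact.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
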