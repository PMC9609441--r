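Package: nanotwin
Title: Digital Twin for Wet-Milled, Spray-Dried Nanosuspension Manufacturing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An in-silico thread for the manufacture of solidified drug
    nanosuspensions. Ranks stabilizer candidates by their interfacial Gibbs
    energy contribution computed from PC-SAFT segment parameters and
    Berthelot-Lorentz combining rules; simulates wet media milling as a
    discrete breakage population balance with de Vegt, Austin and Kapur
    kernel families and fits their tuning parameters to median-size D50(t)
    profiles; augments sparse milling experiments into dense reference
    profiles with a small feed-forward neural network or polynomial
    regression; and simulates spray drying of the milled suspension through
    coupled droplet and gas-phase mass and energy balances advanced by a
    fixed-step backward-differentiation-formula integrator, including
    two-factor design-space mapping of the final moisture content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
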