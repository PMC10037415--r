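Package: gietr
Title: Graphene-Induced Energy Transfer Analysis of Lipid Bilayer Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring nanometric axial distances and supported
    lipid bilayer (SLB) thickness with graphene-induced energy transfer
    (GIET) fluorescence lifetime spectroscopy. Computes lifetime-versus-
    distance calibration curves from first-principles dipole electrodynamics
    above a glass/graphene/SiO2 substrate, fits time-correlated single-photon
    counting (TCSPC) decays with IRF-convolved biexponential models by
    Poisson maximum likelihood, inverts leaflet lifetime pairs into heights
    and bilayer thickness by an iterative thickness-consistent procedure,
    and simulates ground-truth-tagged photon streams for end-to-end
    validation of the full analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
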