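Package: slpsim
Title: Specific Loss Power Modelling for Superparamagnetic Hyperthermia
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling of the specific loss power (SLP, also called
    SAR) dissipated by monodisperse single-domain magnetic nanoparticles in
    an alternating magnetic field, in the linear-response (Debye) regime with
    a Langevin saturation correction. Covers both immobilized particles
    (Neel relaxation only) and core-shell coated particles dispersed in a
    carrier liquid (combined Neel-Brown relaxation with the hydrodynamic
    diameter set by the organic shell). Includes diameter/field/frequency
    sweep machinery with sub-grid peak refinement, relaxation-regime
    classification, Neel-Brown crossover localization, packaged parameter
    presets for gamma-cyclodextrin-coated cobalt ferrite in saline, CSV/JSON
    writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
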