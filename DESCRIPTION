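Package: hyphasim
Title: Tanks-in-Series Simulation of Fungal Hyphal Tip Growth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulator of single fungal hypha extension based on
    a chain of well-mixed cubic tanks. Nutrient supplied by a vegetative
    source tank moves towards the tip by cytoplasmic convection and
    diffusion; a sub-apical zone converts nutrient into wall-building
    vesicles with Michaelis-Menten kinetics; vesicles are actively
    transported to the tip-tank, whose consumption of vesicles extends the
    wall. The tip-tank grows until it reaches twice the normal tank length
    and is then split in two, so the ODE system is re-dimensioned at
    discrete division events. Ships calibrated parameter presets for
    reproductive aerial hyphae of Rhizopus oligosporus, Aspergillus
    giganteus and Phycomyces blakesleeanus, plus spatial-profile,
    vesicle-localization and one-at-a-time parameter sensitivity analyses,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
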