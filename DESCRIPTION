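Package: shelfweb
Title: Guild-Based Nitrogen Mass-Balance Food-Web Model of an Ice-Covered
    Arctic Shelf
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end box model of an Arctic continental-shelf ecosystem
    that tracks nitrogen through nutrients, detritus, plankton, benthos, fish
    and top predators, with a cryosphere coupling (light attenuation by sea
    ice and snow, nutrient entrainment and melt release, ice-dependent
    habitat). Ships a synthetic decadal driver generator emulating
    high-emissions warming and sea-ice retreat, a fixed-step integrator that
    runs the system to steady annual cycles while accumulating a
    compartment-to-compartment flow ledger, ecological network indices
    (trophic level, omnivory, internal ascendancy and capacity, dominance of
    indirect effects, nutrition-mode shares), driver knock-out experiments
    with principal-component summaries, and Morris elementary-effects
    sensitivity screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
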