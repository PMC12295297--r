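Package: ommatidia
Title: Apposition Compound-Eye Optics and Ommatidial Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the optics of small apposition compound
    eyes from ommatidial morphometry. Implements the thick-lens surface-power
    model of the corneal facet (surface powers, total lens power, object- and
    image-side focal lengths, F-number), the photoreceptor acceptance angle,
    the diffraction (Airy disk) half-width, white-light optical sensitivity
    with self-screening absorption, and step-index waveguide V-parameter mode
    analysis of the rhabdom. Ships transcriptions of the morphometric and
    optical tables for the fig wasp Ceratosolen gravelyi and three comparison
    parasitoid wasps, builds multi-species comparison tables under a
    printed-precision reporting policy, generates synthetic ommatidial
    lattices on a spherical eye cap with regional facet-size gradients, and
    propagates measurement uncertainty through the optical model by Monte
    Carlo.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
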