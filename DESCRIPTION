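Package: kelpfe
Title: Iron Speciation and Physiology of Kelp in Ion-Buffered Culture Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing iron-limitation experiments on kelp grown in
    EDTA ion-buffered (Aquil-type) seawater media. Computes inorganic iron
    (Fe') from total dissolved iron and conditional FeEDTA dissociation
    constants, inverts the buffer model to design media for target Fe'
    levels, derives physiological rates (growth, dissolved organic carbon
    flux, oxygen fluxes, photochemical efficiency, tissue stoichiometry,
    soluble nitrate, chlorophyll pigments) from replicate measurements, fits
    Michaelis-Menten dose-response curves of growth against Fe', runs the
    treatment-comparison statistics (normalizing transform selection,
    one-way ANOVA, Tukey HSD, compact letter display), generates seeded
    synthetic experiments with the study design for validation, and places
    culture iron requirements in the context of coastal-to-ocean dissolved
    iron gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
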