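Package: circRNFL
Title: Circular Statistics for High-Resolution OCT RNFL Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for directionally focused analysis of circumpapillary
    retinal nerve fiber layer (RNFL) thickness profiles measured by optical
    coherence tomography at equally spaced angular points in TSNIT order.
    Builds direction-specific empirical normative catalogs stratified by age
    and optic disc size, transforms profiles into Angular Quantile and Angular
    Decay circular sequences, traces contiguous supra-threshold decay regions
    ("petals") with directional summaries (petal count, widest petal, its
    decay-weighted circular mean, local and global loss indices), clusters
    decay directions with finite von Mises mixtures fitted by EM with BIC
    model selection, and refines glaucoma-versus-normal decision-tree
    classification by circular cluster membership. Includes a seeded
    synthetic cohort generator emulating the normal TSNIT double-hump
    profile and focal wedge-shaped glaucomatous defects, plus a command-line
    interface and polar visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rpart
Config/testthat/edition: 3
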