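Package: cmbmars
Title: Size and Anatomical Rating of Cerebral Microbleeds from Binary Lesion Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Characterises cerebral microbleeds (CMBs) from binary lesion masks:
    3D connected-component extraction, moment-matched ellipsoid diameters in
    millimetres, construction of a Microbleed Anatomical Rating Scale (MARS)
    structure atlas from probabilistic and discrete source atlases, transfer of
    the atlas into subject space through a supplied affine, automatic structure-
    and region-wise CMB counting, and lesion-wise evaluation of automated
    ratings against manual references. A synthetic phantom generator provides
    fully self-contained inputs for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
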