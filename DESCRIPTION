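Package: flnr
Title: Deriving the Fraction of Leaf Nitrogen Allocated to RuBisCO from
    Photosynthetic Capacity and Leaf Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive the fraction of leaf nitrogen allocated to
    RuBisCO (fLNR) from maximum carboxylation capacity standardized to 25
    degrees C (Vcmax25) and area-based leaf nitrogen content, and to study
    its environmental drivers. Includes a peaked Arrhenius temperature
    standardization of Vcmax, a bagged-tree upscaling model with
    permutation-importance forward selection and both conventional and
    spatially buffered cross-validation, multi-source bootstrap uncertainty
    propagation for gridded fLNR, a group-PCA plus generalized-additive-model
    attribution of fLNR variation to leaf-trait, climate and soil drivers
    with per-variable linear sensitivities, a zoo of empirical Vcmax25
    models and map-comparison statistics, and a seedable synthetic-globe
    generator so the whole chain is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    mgcv,
    ncdf4,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
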