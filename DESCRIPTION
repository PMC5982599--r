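Package: melspect
Title: Dual-Modality Multispectral Reflectance Analysis of Pigmented Skin Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discriminating melanomas from nevi with
    combined visible/near-infrared (414-995 nm, 12-bit CCD) and extended
    near-infrared (995-1613 nm, 16-bit InGaAs) multispectral reflectance
    image stacks. Implements flat-field/dark-frame reflectance calibration
    against a gray reference, quadrant-wise Otsu lesion segmentation with
    similarity-transform mask transfer between the two camera grids,
    first-order histogram descriptors (mean, extrema, standard deviation,
    energy, entropy, third central moment) over reflectance and absorbance
    variants, greedy threshold-rule descriptor selection, and SVD-based PCA
    with a support-vector-machine decision boundary reporting sensitivity
    and specificity. Ships a dual-modality lesion phantom generator so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    png,
    jsonlite,
    e1071,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
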