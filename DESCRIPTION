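Package: gbcaPET
Title: Gadolinium Contrast Agent Effects on PET Attenuation and Quantification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models the effect of gadolinium-based MR contrast agents (GBCA) on
    the 511 keV linear attenuation coefficient of a radiotracer solution and on
    quantitative PET, at phantom scale. Implements the Hubbell weighted-average
    mixture rule for the mass attenuation coefficient of a water/GBCA solution,
    dilution-series mass bookkeeping for a cylindrical phantom, a synthetic CT
    chain with bilinear Hounsfield-unit to 511 keV conversion, a parallel-beam
    projector with filtered back-projection reconstruction, and three
    attenuation-correction strategies (matched CT map, fixed zero-contrast CT
    map, uniform 0.1 per-cm map) whose activity-concentration bias is tabulated
    against decay- and volume-corrected ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
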