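Package: mrpct
Title: MRI Intensity Normalization and Pseudo-CT Synthesis for Torso Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Normalizes the intensities of non-bone tissues in volumetric
    torso MRI to common per-tissue levels by dividing the image by a shading
    map, i.e. a smoothed ratio between the MRI and a three-intensity mask
    built from a fuzzy c-means tissue segmentation.  Converts normalized MRI
    into pseudo-CT (Hounsfield units) via pointwise MRI-CT intensity pairs
    sampled from rigidly registered image pairs, phantom-template images, and
    a small three-stage valid-convolution patch network with deep
    supervision.  Ships a digital torso-phantom simulator with known tissue
    labels, bias field and noise so that every stage can be verified without
    patient data, plus tissue-wise evaluation reports and an end-to-end
    pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
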