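Package: cobbnet
Title: Computer-Aided Cobb Angle Measurement from Neural-Network Vertebral
    Slope Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computer-aided measurement of the Cobb angle on
    posteroanterior spinal radiographs. A regression network with a
    principal-component first layer and two hyperbolic-tangent hidden
    layers predicts the endplate slope of a vertebra from a 150x150 pixel
    image patch; the Cobb angle of a curve is the sum of the absolute
    slopes of the two most tilted, oppositely inclined vertebrae.
    Includes a synthetic spine-phantom radiograph generator with exact
    per-vertebra ground-truth slopes and pedicle lead markers, a patch
    extraction and downsampling pipeline, layer-wise autoencoder
    pretraining with backpropagation fine-tuning, and reliability
    analysis (intraclass correlation with confidence intervals, mean
    absolute difference) for simulated examiner studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
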