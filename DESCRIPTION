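Package: strainsight
Title: Quantification of LIM-Domain Reporter Recruitment to Stressed Actin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-quantification pipelines for fluorescence microscopy of
    LIM-domain reporters on mechanically stressed actin. Implements a
    reference-mask enrichment score for two-channel images (construct
    channel scored against a Zyxin-LCR reference mask) and a time-lapse
    bright-object counter for myosin-inhibition experiments, on top of
    from-scratch implementations of the underlying operators: sliding
    paraboloid / rolling ball background subtraction, Gaussian blur,
    Triangle and Renyi-entropy automatic thresholding, binary erosion and
    connected-component particle filtering. A synthetic two-channel scene
    and time-lapse generator with known ground truth makes every stage
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
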