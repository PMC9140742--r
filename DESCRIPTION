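Package: pupilmetry
Title: Pupil Diameter Estimation from Smartphone Eye Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates pupil diameter time series from sequences of RGB eye
    images captured with consumer smartphone cameras, where dark irises make
    grayscale segmentation unreliable. Implements two color-based pipelines: a
    running-minimum low-pass filter over 3x3 red-channel window means with an
    adaptive component threshold for outdoor-sunlight images (CCLPF), and an
    HSV saturation sweep with a pixel-growth-ratio stopping rule for
    indoor-flash images (PRSSM). Includes a Canny/Hough circle detection
    baseline for comparison, shared morphology and contour-based diameter
    measurement with rule-of-thumb temporal correction, a seeded synthetic
    eye-image generator with ground-truth diameters, and a command-line
    interface for generating, analyzing, and evaluating image sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    grDevices,
    igraph,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
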