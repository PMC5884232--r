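Package: mtjtrack
Title: Automatic Myotendinous Junction Tracking in Ultrasound Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phase-based segmentation and tracking of the myotendinous junction
    (MTJ) in B-mode musculoskeletal ultrasound sequences. Tendinous tissue is
    enhanced with oriented phase congruency computed from a log-Gabor quadrature
    filter bank, the two aponeuroses are detected with a localized Radon
    transform with iterative revoting, and an effective MTJ region is derived by
    distance banding and Otsu thresholding. The MTJ is then tracked across
    frames as the intersection of the two aponeurosis lines, advected by a
    global affine Lucas-Kanade optical flow fitted by least squares over the
    segmented region only, which suppresses the influence of independently
    moving non-tendinous tissue and speckle. Includes a speckle phantom
    generator with known ground-truth geometry and motion, and waveform
    agreement statistics (coefficient of multiple correlation, intraclass
    correlation, Bland-Altman limits of agreement, polynomial angle-displacement
    regression).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
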