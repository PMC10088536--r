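Package: ebusdepot
Title: Quantifying Intratumoral Drug Depots in Endobronchial Ultrasound Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the appearance, geometry and retention of an
    intratumorally injected drug depot in B-mode endobronchial ultrasound
    (EBUS) video. Provides a synthetic speckle-video simulator with known
    ground truth, region-of-interest intensity screening, background
    subtraction with edge-preserving despeckling and cluster thresholding for
    depot segmentation, exponential-plateau uptake kinetics with derived
    injection duration and flow rate, needle-frame shape metrics (centroid
    paths, Feret diameters, solid-of-revolution retention volumes), and a
    physical-mechanism layer contrasting radial Darcy porous flow against
    crack-tunneling tissue fracture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    zoo
Config/testthat/edition: 3
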