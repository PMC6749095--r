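Package: incluflux
Title: Quantitative Microscopy of Mobile, Exchanging Protein Inclusions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative fluorescence
    microscopy of huntingtin-like inclusion bodies in yeast: single-particle
    tracking (Laplacian-of-Gaussian spot enhancement plus dynamic-programming
    linking), mean-squared-displacement analysis with anomalous-diffusion
    exponent and diffusion-coefficient estimation, inclusion morphometry
    (threshold segmentation, circularity, aspect ratio, apparent volume,
    chance-overlap probability), FRAP recovery quantitation, and
    photoconversion pulse-chase flux analysis with exponential photobleaching
    calibration and correction. A seeded synthetic-microscopy generator
    (Brownian and directed trajectories, rendered time-lapse movies and
    z-stacks, two-pool two-colour pulse-chase kinetics with cell-division
    dilution) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
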