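Package: brushsim
Title: Virtual Imaging Trials for End-Expandable Fiber-Bundle Microendoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for evaluating an end-expandable ("brush")
    optical fiber microendoscopy probe before hardware prototyping. Generates
    synthetic high-resolution microendoscopy phantoms with labeled nuclear
    density classes, reproduces the standard preprocessing chain (size
    standardization, Gaussian de-combing, contrast-limited adaptive histogram
    equalization), degrades images through a parameterized sparse-fiber
    acquisition model (fiber diameter, inter-fiber distance, deformation
    offset), restores them with a three-layer super-resolution convolutional
    network trained by backpropagation, and evaluates results with PSNR/SSIM
    image-quality metrics and diagnostic reader-study statistics (confusion
    matrices, sensitivity/specificity/accuracy, unpaired t-tests, equivalence
    sample-size planning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    withr,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
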