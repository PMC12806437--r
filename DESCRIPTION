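Package: hextomo
Title: Wedge-Based Dynamic X-Ray Tomography via Hexplane Neural Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-supervised 4D reconstruction of time-evolving refractive-index
    volumes n(x,t) from narrow angular wedges of parallel-beam X-ray
    radiographs. A six-plane (hexplane) tensorial factorization of spacetime
    feeds a small multilayer perceptron that decodes the refractive-index
    decrement (delta) and attenuation index (beta) at any spatiotemporal
    point; radiographs are rendered through a differentiable line-integral
    forward model under the projection approximation and the scene is fitted
    by minimizing a mean-squared-error data term with total-variation and L1
    plane regularizers. The package also provides the wedge acquisition
    scheduler and extraction from continuous-rotation tomoscopy stacks,
    radiograph preprocessing (flat-field correction, single-distance
    transport-of-intensity phase retrieval, Radon-sum normalization,
    half-to-full rotation rebinning), a filtered-back-projection baseline,
    Fourier shell correlation with the half-bit resolution criterion,
    PSNR/SSIM/NRMSE scoring, synthetic dynamic phantoms with a virtual
    tomoscopy acquisition, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
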