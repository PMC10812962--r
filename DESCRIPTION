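Package: qmapsynth
Title: Synthesis of Quantitative T1rho Maps from T2 Maps in Knee MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A phantom-driven pipeline for quantitative knee MRI map
    synthesis. Simulates multi-echo spin-lock (T1rho-weighted) and
    T2-prepared image series over stylized cartilage compartment
    phantoms, fits mono-exponential relaxation maps by vectorized
    Levenberg-Marquardt least squares, trains a compact 2D U-Net with a
    cartilage-weighted loss to synthesize T1rho maps from T2 maps, and
    evaluates agreement with masked NMSE, PSNR, SSIM, Pearson
    correlation, Bland-Altman limits of agreement and a compartment-mean
    quantification-error rate, including out-of-distribution coil-bias
    and SNR stress tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
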