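Package: estimact
Title: Estimability-Index Prediction of CT Lesion Volumetry Precision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fourier-domain prediction of the precision of lesion volume
    quantification in computed tomography. Implements the estimability index
    e' from the three-dimensional noise power spectrum (NPS), the task
    transfer function (TTF), a nodule task function built from the lesion's
    Laplacian edge profile, and a segmentation template function; the
    empirical precision arm as the percent repeatability coefficient (PRC)
    from repeated volume measurements; the logarithmic calibration relating
    the two; and a synthetic CT simulator (spectrally shaped noise, blurred
    edge phantoms, spherical nodule scenes with seeded repeats) that makes
    the whole chain testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
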