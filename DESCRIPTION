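Package: crbsvd
Title: Cramer-Rao Bound Preserving Subspace Bases for Quantitative MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing temporal subspace bases for quantitative MRI
    that jointly preserve signal energy and the Cramer-Rao bound (CRB) of the
    biophysical parameters. Implements an analytic inversion-recovery/decay toy
    model and an isochromat-ensemble FISP fingerprinting simulator, fingerprint
    dictionary construction, orthogonalized signal derivatives, the
    uncompressed, approximate-compressed and exact-compressed CRB, the CRB-SVD
    basis obtained from the singular value decomposition of a concatenated
    signal/derivative matrix, dictionary-matching and nonlinear least squares
    estimators with a Monte-Carlo bias/variance harness, and a minimal
    Cartesian subspace image reconstruction demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
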