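Package: stereojoint
Title: Design-Based Stereology of Synovial Joints with Phantom Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based stereological estimation for small synovial joints
    sectioned under the vertical uniform random design: Cavalieri volume with
    the Gundersen-Jensen coefficient-of-error prediction, Delesse volume
    fractions and absolute compartment volumes, cycloid-based surface densities
    and absolute surface areas, and chondrocyte profile densities from unbiased
    counting frames. Includes parametric nested-shell joint phantoms with
    analytic or quadrature ground truth, a virtual vertical-sectioning and
    probe-counting simulator with reproducible hierarchical seeding, a
    section-reduction efficiency analysis, and group-comparison statistics, so
    every estimator can be validated by Monte Carlo against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
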