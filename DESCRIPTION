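Package: volresp
Title: Volumetric and Bidimensional Tumor Response Assessment for Pediatric Low-Grade Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing two-dimensional (bidimensional product) and
    volumetric response assessment of pediatric low-grade glioma in longitudinal
    imaging studies. Implements the RANO/RAPNO threshold rule sets together with
    their sphere-extrapolated volumetric counterparts, concordance statistics
    against visual BT-RADS assessment (empirical ROC curves, stratified-bootstrap
    AUC confidence intervals, the paired DeLong test, threshold sensitivity sweeps,
    weighted kappa inter-reader agreement), and a mechanistic exponential
    growth/treatment-response/resistance-onset model of solid tumor volume fitted
    by ensemble Markov chain Monte Carlo with measurement-noise bootstrapping and
    trajectory-based response classification. A seeded synthetic cohort generator
    reproduces the statistical structure of such trials so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
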