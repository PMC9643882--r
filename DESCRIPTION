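Package: bloodspec
Title: FT-NIR Authentication of Blood-Based Foods by Fast Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and chemometric analysis of Fourier-transform
    near-infrared (FT-NIR) spectra for authenticating duck blood tofu
    adulterated with cow or pig blood-based gels. Provides a synthetic
    spectra generator (Gaussian absorption bands, Beer-Lambert mixing,
    multiplicative/additive scatter artifacts, replicate averaging),
    spectral pretreatments (centering, Savitzky-Golay derivatives, SNV,
    MSC), Kennard-Stone sample partitioning, variable selection by
    stepwise discriminant analysis (SWDA) and competitive adaptive
    reweighted sampling (CARS), six-class identification via PCA, Fisher
    linear discriminant analysis and extreme learning machine (ELM)
    classifiers, and adulteration-level quantification via ELM regression
    evaluated with RMSE, r, RPD and RER.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    signal,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
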