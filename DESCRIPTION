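Package: wardtrig
Title: Ambient Environmental Triggers of Agitation Subtypes on Dementia Wards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links ambient environmental conditions (light, sound, temperature)
    on a psychogeriatric ward to momentary agitation and its motor and verbal
    subtypes rated with the Pittsburgh Agitation Scale during experience
    sampling. Provides a synthetic ward generator with known generative
    parameters, location-conditioned pre-survey window extraction with sensor
    fusion and smoothing, descriptive-feature computation with quality
    filtering and within-room standardization, random-intercept binomial
    generalized linear mixed models fitted by adaptive Gauss-Hermite
    quadrature, likelihood-ratio model comparison, window-length and feature
    selection sweeps, and a forward model build-up mirroring the staged
    analysis, all orchestrated by a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
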