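Package: spongeforage
Title: Prey-Abundance Pipeline and Exact Paired Tests for Sponge-Foraging
    Transect Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing paired belt-transect surveys of benthic
    prey availability, built around the Shark Bay sponge-foraging study
    design: seven transects each sampled in a substrate-disturbing
    ("sponging") and a non-disturbing ("non-sponging") mode, with
    replicate passes and additional verification dives.  Provides the
    filtering and aggregation rules that turn raw prey encounters into
    family-level abundance tables, a pseudocount ratio statistic, an
    exact paired Wilcoxon signed-rank test computed by full sign-vector
    enumeration, a Monte Carlo family-resampling test against a
    historical prey universe with an analytic binomial cross-check, a
    seed-reproducible synthetic study generator, and an end-to-end
    pipeline that emits a structured JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
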