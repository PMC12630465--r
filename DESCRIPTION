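Package: standbench
Title: Demographic Benchmarking of Forest Stand Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking the demographic behaviour of vegetation
    demographic models (VDMs) from annual stand-level output tables. Verifies
    demographic woody-carbon budget closure, computes fractional mortality
    rates and woody carbon turnover times with left-aligned rolling smoothing,
    detects self-thinning periods by four methods and fits the self-thinning
    slope in log mass-density space, classifies forest-recovery phases
    (grass coexistence, open-canopy growth, closed-canopy self-thinning,
    late-successional) and aligns model runs on a common phase timeline, and
    builds observation envelopes (chronosequence age bins, dbh-class
    structure ranges, spatial plot bootstraps) to score model output against.
    A synthetic cohort-demography generator provides stand series with exact
    embedded ground truth so every pipeline stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    zoo,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
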