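Package: protrial
Title: Longitudinal Plasma-Proteomics Response Markers and Two-Arm Trial Statistics
Version: 0.1.0
Authors@R:
    person("Plasma Proteomics Trial Analytics Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Analysis pipeline for randomized two-arm oncology trials with
    paired pre/post-treatment plasma proteomes. Per-protein linear mixed
    models with a patient random intercept are tested against four contrast
    families (pre-treatment response differences within arm, arm-by-response
    interactions, pre/post changes within response cells, and arm-by-time
    interactions), with Benjamini-Hochberg multiplicity adjustment and
    compound decision rules that call arm-specific response markers and
    treatment targets. Also provides spectral-count preprocessing
    (detection filtering, total-count normalization, log transform),
    single-protein and multi-protein panel ROC prediction of response,
    composite mRECIST response classification over intra- and extrahepatic
    lesions, response-rate endpoints with exact intervals, Kaplan-Meier and
    log-rank survival comparison, Freedman/Schoenfeld log-rank sample-size
    design, and a synthetic-cohort generator with known spike-in ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
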