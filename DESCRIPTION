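Package: gazegrad
Title: Saccadic Reaction Time Extraction and Household-Resource Gradient
    Estimation from Infant Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting saccadic reaction times (SRT) and
    social-cue latencies from remote eye-tracker gaze streams recorded in
    infant and toddler cohorts, and for estimating socioeconomic gradients
    in these latencies. Implements binocular gaze merging, NA-aware median
    filtering, area-of-interest entry detection under explicit trial
    validity criteria, log-scale outlier exclusion, participant retention
    rules, split-half and cross-visit reliability, an asset-based household
    wealth index (first principal component of standardized asset
    indicators), and linear mixed-effects models of latency on the wealth
    index with covariate-adjusted and replication-cohort variants. A
    synthetic cohort and gaze-session generator with complete ground truth
    supports end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
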