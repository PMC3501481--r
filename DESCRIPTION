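Package: dmnclass
Title: Task-Induced Deactivation and Default Mode Network Connectivity
    Classification for Blocked-Design fMRI
Version: 0.1.0
Authors@R: person("DMN", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the default mode network (DMN) from
    blocked-design fMRI studies: extraction of a pseudo-resting-state
    series by excising fixation blocks (with hemodynamic-lag trimming),
    nuisance regression (motion, tissue and global means, per-session
    trends), task-deactivation GLM contrasts with FDR and Monte-Carlo
    cluster-extent thresholding, seed-based and ROI-by-ROI functional
    connectivity with Fisher r-to-z maps, and leave-one-out logistic
    regression classification of group membership with exact binomial
    significance.  Includes a synthetic two-group cohort generator with
    planted connectivity and deactivation effects so the whole pipeline
    is testable without any scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
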