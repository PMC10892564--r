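Package: stepcadence
Title: Cadence-Based Digital Biomarkers for Rehabilitation Monitoring
Version: 0.1.0
Authors@R: person("stepcadence", "developers", role = c("aut", "cre"),
    email = "maintainers@stepcadence.dev")
Description: Tools for monitoring recovery after hip and knee arthroplasty
    from minute-resolution wearable step-count streams. Computes per-day
    digital biomarkers (daily steps, peak 1-minute cadence, peak 6-minute
    consecutive cadence, cadence-band intensity minutes), quantifies
    intraweek variability, stratifies patients by whether the Forgotten
    Joint Score change at 3 months reaches the minimal clinically important
    difference, and models recovery trajectories with a random-intercept
    linear mixed model to estimate time-to-return-to-baseline and the
    earliest day at which recovery groups separate. Includes a calibrated
    synthetic-cohort generator with known ground truth and a command-line
    pipeline (simulate / summarize / analyze).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
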