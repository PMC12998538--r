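Package: noctvar
Title: Night-to-Night Sleep Variability via Mixed-Effects Location-Scale Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for longitudinal analysis of night-to-night sleep variability
    from epoch-scored hypnograms, as produced by contactless (radar) sleep
    monitors. Derives nightly sleep parameters (adjusted sleep latency, total
    sleep time, wake after sleep onset, final awakening, time in bed, sleep
    efficiency) from 30-second epoch sequences with an absence-aware analysis
    window; fits a mixed-effects location-scale model by maximum likelihood to
    estimate group means and group-specific within-subject standard deviations
    with a subject random intercept and covariate adjustment; and reports
    planned Wald contrasts with confidence intervals. Includes a synthetic
    cohort generator with subject random intercepts, group-specific
    night-to-night variability, pre-sleep absence bouts, and weekly adherence
    decline, so the full pipeline is testable without access to raw device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    nlme,
    pracma,
    jsonlite
Config/testthat/edition: 3
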