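Package: cognorm
Title: Normative Scoring and Psychometric Validation for Web-Based Cognitive Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds age-binned normative tables for multi-subtest cognitive
    batteries via the percentile rank-based inverse normal transformation,
    scores individuals on a mean-100/SD-15 scale including a battery-level
    Grand Index, and provides the psychometric validation toolkit that
    accompanies such norms: test-retest reliability with analytic and
    bootstrap confidence intervals, Fisher r-to-z comparison of correlations,
    inter-test-interval and engagement moderation analyses, inter-subtest
    correlation structure (dendrogram, parallel analysis, maximum-likelihood
    factor analysis with varimax rotation and RMSEA), demographic-effect
    regression, Welch and ANOVA group comparisons, and repeated exact
    case-control matching. A calibrated latent-factor cohort simulator makes
    the full pipeline testable end to end without access to proprietary
    user data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    sandwich,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
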