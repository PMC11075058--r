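Package: chordmaps
Title: Information Dynamics of Chord Progressions, Bodily Sensation Maps and
    Emotion Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how musical expectancy shapes bodily
    sensation and emotion. Fits a first-order transition model to a symbolic
    chord corpus and derives per-chord surprisal (information content) and
    entropy (uncertainty) in bits; designs four-chord stimuli stratified into
    eight surprise-by-uncertainty progression types via pooled 20 percent
    quantile thresholds; quantifies body-map click responses into anatomical
    region counts and downsampled heat maps; converts ranked top-5 emotion
    selections into 33-category scores with a sparse-category filter; and runs
    the accompanying statistical battery (Shapiro-Wilk gate, tie-corrected
    Friedman ANOVA with Durbin-Conover post hoc and FDR, Spearman
    correlations, paired contrasts with Cohen's d, random-intercept count
    models, and bootstrap mediation with a robust mediator regression). A
    synthetic-cohort generator with planted, recoverable effects makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
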