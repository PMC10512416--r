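Package: emoroc
Title: Signal Detection Analysis of Auditory Emotion Detection in Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rating-scale signal detection experiments on vocal
    emotion detection in noise. Generates the session/trial structure of a
    four-emotion target-detection task, prepares speech-in-noise stimuli at a
    prescribed signal-to-noise ratio, simulates confidence-graded observers
    from a Gaussian evidence model with trait-anxiety-dependent sensitivity,
    scores responses into corrected-rate empirical ROC curves and empirical
    AUC (eAUC) per emotion, and runs the group-level inference: anxiety-by-
    emotion mixed ANOVA with partial eta squared and Bonferroni simple main
    effects, Mann-Whitney U tests with rank-based effect sizes, plus
    normality (Lilliefors / Kolmogorov-Smirnov) and Mauchly sphericity
    checks and an a priori power utility for the within-between interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    nortest,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
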