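Package: pupilinfo
Title: Information-Theoretic Modeling of the Feedback-Locked Pupil Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating task-evoked pupil dilation to the
    information-theoretic variables of a Dirichlet-categorical ideal
    observer. Provides sequential belief updating with per-trial Shannon
    surprise, posterior entropy and Kullback-Leibler information gain; a
    pupillometry preprocessing chain (artifact detection, padded linear
    interpolation, zero-phase Butterworth band-pass filtering, FIR
    deconvolution nuisance regression, percent signal change);
    feedback-locked epoch extraction with baseline and window summaries;
    trial-wise correlation time courses with Fisher-z group inference,
    cluster-based sign-flip permutation tests, false discovery rate
    control, repeated-measures ANOVA with Greenhouse-Geisser correction,
    Wilcoxon signed-rank contrasts, and random-intercept mixed-model
    comparison via cross-validated expected log predictive density.
    Includes generators for probabilistic cue-target, odd-ball exposure
    and letter-color decision designs plus synthetic pupil recordings with
    planted effects, so the full pipeline is testable end to end without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
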