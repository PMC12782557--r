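# pupilinfo

Information-theoretic modeling of the feedback-locked pupil response
during associative learning.

Task-evoked pupil dilation tracks central arousal and is notably
sensitive to unexpected events. `pupilinfo` is for researchers who want
to ask a sharper question of their pupillometry data: does the pupil's
response to trial feedback reflect *how much was learned*? The package
pairs a Dirichlet-categorical ideal observer with a complete pupil
analysis chain, so the per-trial quantities of an optimal learner can be
regressed against the evoked pupil response, with the inferential
machinery (cluster-corrected permutation tests, repeated-measures
ANOVAs, mixed-model comparison) that this literature uses.

## The model

An ideal observer watches discrete events `x^j ∈ {1..K}` and keeps a
Dirichlet belief over the event probabilities. With prior concentrations
`α` and counts `n_k` after `j − 1` trials, the predictive probability of
event `k` on trial `j` is

    p̃_k = (n_k + α_k) / (j − 1 + Σ α)

and each trial yields, in bits:

* surprise `I = −log2(p̃_k)` of the observed event (pre-update belief),
* entropy `H = −Σ p_k log2 p_k` of the posterior mean including the
  trial,
* information gain `D_KL = Σ p_k^post log2(p_k^post / p_k^pre)`, the KL
  divergence between the post- and pre-update posterior means.

Two task designs are built in as generative specifications: a
probabilistic **cue-target** 2AFC (K = 4, uniform prior, 80/20
contingencies; entropy falls as the observer learns) and a
**letter-color** 2AFC whose prior is estimated from an odd-ball exposure
phase (K = 36, concentrated prior, balanced presentation; entropy
rises). The preprocessing chain (padded interpolation, derivative-spike
detection, zero-phase 0.01–6 Hz Butterworth filtering, FIR deconvolution
of blink/saccade responses, percent signal change), epoch extraction with
baseline and early/late window summaries, and the statistics layer are
all exposed as composable functions; `runPipeline()` wires them
end-to-end on synthetic data with planted, recoverable effects.

## Worked example

```r
library(pupilinfo)

# one participant's cue-target sequence and learner quantities
design <- genCueTargetSequence(nTrials = 200, seed = 42)
info <- runLearner(design$event, uniformPrior(4))
head(info, 4)
#>   trial event p_pred     I     H     DKL
#> 1     1     1 0.2500 2.000 1.922 0.07807
#> 2     2     1 0.4000 1.322 1.792 0.02945
#> 3     3     4 0.1667 2.585 1.842 0.06332
#> 4     4     1 0.4286 1.222 1.750 0.01487

# end-to-end synthetic study: 8 participants, planted information-gain
# loading of 50 (% signal change per bit) on the pupil amplitude
cfg <- analysisConfig(task = "cue_target", nSubjects = 8, nTrials = 60,
                      betas = list(beta0 = 2, betaDKL = 50),
                      amplitudeNoiseSd = 1, sampleNoiseSd = 2,
                      blinkRatePerMin = 2, nPerm = 1000, nFolds = 5,
                      seed = 42)
bundle <- runPipeline(cfg)

bundle$clusters$DKL$clusters
#>   start_s end_s mass p_value
#> 1     0.3  1.92 1018   0.007
```

The information-gain correlation time course carries a significant
cluster from 0.3 to 1.9 s after feedback — spanning the early analysis
window [0.75, 1.25) s around the canonical impulse-response peak, where
the loading was planted. The mixed model sees the same effect:

```r
co <- bundle$hlm$model1$coefficients
co[co$term == "DKL", ]
#>     term estimate lower upper  pd
#> DKL  DKL     33.9  28.1  39.7 100
```

(The window-mean estimator's gain is the mean of the unit-peak impulse
response over the window, `irfWindowGain(c(0.75, 1.25), fs = 50)` ≈ 0.89,
and the trace-level baseline covariate absorbs part of the planted
effect — see the methods vignette; table-level recovery of the planted
coefficient is unbiased.)

```r
bundle$hlm$ratio      # |ΔELPD| / SE = 1.51 — below 2:
bundle$hlm$preferred  # Model 1; the H × D_KL interaction is not supported
```

`writeReport(bundle, "out/")` serializes the trial table, correlation
time courses, cluster tables, ANOVA and model-comparison results as
TSV/JSON plus a plain-text summary. A thin command-line wrapper around
the same functions is installed at `inst/scripts/run_pipeline.R`.

## Method references in the vignette

`vignettes/pupilinfo-methods.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generators do and do not emulate, the numerical choices
(window conventions, filter topology, FIR basis, ELPD backend), and
known limitations.
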