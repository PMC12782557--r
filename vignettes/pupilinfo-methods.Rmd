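---
title: "Modeling the feedback-locked pupil response with an ideal learner"
author: "pupilinfo maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the feedback-locked pupil response with an ideal learner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilinfo)
```

# The scientific problem

Task-evoked pupil dilation under constant luminance tracks central arousal,
and a long line of work ties it to the processing of unexpected events.
`pupilinfo` implements an information-theoretic account of the pupil's
response to *feedback* during associative learning: an ideal observer
watches the same stimulus stream as the participant, updates a belief about
the event probabilities after every trial, and three per-trial quantities
summarise what the feedback delivered — how improbable the event was
(surprise), how uncertain the observer now is (entropy), and how much the
belief moved (information gain). The package relates these quantities to
the feedback-locked pupil response with trial-wise correlation time
courses, cluster-corrected permutation inference, factorial window
statistics, and random-intercept mixed models.

# The ideal learner

The observer watches discrete events $x^j \in \{1, \dots, K\}$ and holds a
Dirichlet belief over the event probability vector $p$. With prior
concentrations $\alpha$ and event counts $n_k^j$ after $j$ trials, the
posterior is $\mathrm{Dir}(\alpha + n^j)$ and its mean assigns

$$\tilde p_k^{\,j} = \frac{n_k^{\,j-1} + \alpha_k}{j - 1 + \sum_k \alpha_k}$$

to event $k$ on trial $j$. The three per-trial quantities, all in bits:

* **Surprise** $I = -\log_2 \tilde p_k^{\,j}$, computed from the belief
  *before* the trial is absorbed — the observer is surprised relative to
  the prediction it could actually have made.
* **Entropy** $H = -\sum_k p_k^{\,j} \log_2 p_k^{\,j}$ of the posterior
  mean *including* the trial — by the time feedback is processed, the
  trial's outcome is known.
* **Information gain** $D_{KL} = \sum_k p_k^{\,j} \log_2 (p_k^{\,j} /
  p_k^{\,j-1})$, the Kullback-Leibler divergence from the pre-update to
  the post-update posterior mean (categorical KL of the mean vectors, not
  KL between full Dirichlet densities).

A textbook presentation writes the predictive denominator as $j - 1 + K$,
which only normalizes when $\sum_k \alpha_k = K$. We generalize to
$j - 1 + \sum_k \alpha_k$ so that any positive prior yields a proper
distribution; with the default prior scaling the two forms coincide.

Probabilities are clipped at $10^{-12}$ before logarithms as a guard;
with positive concentrations the bound never binds.

## Priors for the two task designs

**Cue-target design (K = 4).** Two cue shapes each predict one of two
target orientations on 80 % of that cue's trials. The observer starts
uninformed: $\alpha = [1,1,1,1]$. Because the event frequencies are
skewed (0.4/0.1/0.4/0.1), entropy *decreases* as the observer learns.

**Letter-color design (K = 36).** Six letters and six colors are first
experienced incidentally during an odd-ball detection task; the
decision-phase observer starts from the final exposure probabilities
$P_o$. We estimate them by add-one smoothing over the regular
(non-odd-ball) trials, $P_{o,k} = (n_k + 1) / (N_{reg} + 36)$,
renormalized; odd-ball trials are skipped entirely — they carry no
letter-color event and do not advance the observer. Whether the original
analysis used the probability vector itself or scaled pseudo-counts as
concentrations is ambiguous; both are supported
(`probabilityPrior(..., scaleMode =)`), and the default multiplies by
$K$ so concentrations sum to $K$ and the textbook denominator is
recovered. Because the decision phase presents all 36 pairs in a balanced
way while the prior is concentrated, entropy *increases* over trials —
the mirror image of the cue-target design, which is what makes the pair
of designs jointly informative.

# Preprocessing chain

`preprocessPupil()` applies, in order:

1. **Padded linear interpolation** across annotated missing/blink/saccade
   intervals, each expanded by 0.15 s on both sides (overlaps merged,
   edge gaps filled with the nearest retained value).
2. **Derivative-spike detection**: samples whose absolute first
   difference exceeds a threshold are flagged and interpolated the same
   way. The conventional "10 units per sample" figure presumes a 500 Hz
   device; the pipeline therefore resolves its default threshold as a
   rate of change of 5000 units/s expressed per sample at the actual
   sampling rate. The threshold is in device units and must be adapted to
   the hardware.
3. **Band-pass filtering**, 0.01–6 Hz, third-order Butterworth, applied
   as a cascade of high-pass and low-pass sections forward and backward
   (zero phase, so feedback-locked latencies are not shifted). A direct
   sixth-order band-pass with a relative low cutoff of $4 \times 10^{-5}$
   is numerically fragile in transfer-function form; the cascade is not.
4. **Nuisance deconvolution**: per artifact kind (blink, saccade), a
   finite impulse response over [0, 6] s is estimated by ordinary least
   squares on a linear-interpolation (hat-function) basis with 20 Hz knot
   spacing, events placed at the *end* of each artifact interval; the
   fitted nuisance signal is subtracted. The hat basis represents smooth
   kernels to second order, so a planted noiseless kernel is recovered
   essentially exactly.
5. **Percent signal change** relative to the temporal mean of the
   *interpolated, pre-filter* trace. The residuals themselves are
   near-zero-mean (the high-pass removes DC), so the reference must come
   from before filtering for the scaling to be meaningful.

Epochs are cut at [−0.5, 3.0] s around each feedback onset with
nearest-sample alignment. The per-trial baseline is the mean over
[−0.5, 0) s and is subtracted from the whole epoch; the analysis windows
are half-open, **early** [0.75, 1.25) s (centered on the canonical
impulse-response peak near 0.93 s) and **late** [2.5, 3.0) s (the longest
interval guaranteed uncontaminated by the next trial). Trials whose RT is
more than 3 SD from the participant's mean (z-transform rule) can be
excluded with `excludeRtOutliers()`.

# Statistics

**Correlation time courses.** Per participant and epoch timepoint, the
Pearson correlation across trials between a model variable and the pupil
value; Fisher-transformed ($z = \operatorname{atanh} r$, $r$ clamped away
from $\pm 1$), averaged over participants on the z scale, displayed as
$\tanh(\bar z)$. Participants with zero-variance regressors are
missing-coded and excluded from group inference with a warning.

**Cluster-based permutation test.** One-sample t statistics per
timepoint; contiguous same-sign runs exceeding the two-sided critical
value at $\alpha = 0.05$ form clusters whose mass is the summed t; the
null is the maximum absolute cluster mass over sign flips of participant
rows (default 10,000; the acceptance simulations use 500–1000), p = the
proportion of the null at or above the observed mass, deterministic given
the recorded seed. Where a cluster test does not apply,
`fdrAdjust()` provides Benjamini-Hochberg control.

**Window statistics.** `windowFactorialAnova()` runs fully within-subject
2- and 3-way ANOVAs on per-participant cell means, computed from
orthonormal contrast scores. Greenhouse-Geisser epsilon corrects p values
for effects with ≥ 2 numerator df, and generalized eta squared
($SS_{effect}$ over $SS_{effect}$ plus all subject-linked error SS) is the
effect size. Participants with missing cells are excluded and reported.
`pairedNonparametricTest()` is the Wilcoxon signed-rank contrast with the
matched rank-biserial effect size $(W^+ - W^-)/(W^+ + W^-)$; the exact
null distribution is used up to n = 25 (ties permitting), the
tie-corrected normal approximation beyond.

**Mixed models.** Model 1 is
`pupil ~ I + H + DKL + baseline + rt + (1 | subject)`; Model 2 adds the
`H:DKL` interaction. Models are fit by maximum likelihood (`lme4`) and
compared on a K-fold cross-validated expected log predictive density
(ELPD): held-out Gaussian log predictive densities under the training
fit, folds stratified within subject so every training set contains every
subject. The difference is deemed meaningful only when
$|\Delta \mathrm{ELPD}| / \mathrm{SE} > 2$, with the SE taken from the
pointwise differences. This is a deliberately light-weight backend chosen
for determinism and speed; it preserves the comparison contract of a
fully Bayesian fit (posterior-interval analogues are Wald intervals, and
the direction probability is the Gaussian tail probability of the
coefficient sign) without MCMC.

# The synthetic-data generators

The generators define the study conditions under which everything is
tested:

* `genCueTargetSequence()` — 200 trials, cues split 50/50, the mapped
  orientation on exactly 80 % of each cue's trials (exact-count
  composition, matching a design that fixes proportions; an i.i.d.
  variant is available), two counterbalanced mappings.
* `genOddballSequence()` — 660 trials with 60 odd-balls. Nine percent of
  660 is 59.4, which is not realizable; 60 is the nearest count
  divisible across the odd-ball types and is configurable. The 600
  regular trials show six letters 100 times each; a letter with intended
  association frequency $f \in \{0.2, 0.4, 0.8\}$ shows its associated
  color with probability $f$ and otherwise a uniform draw from all six
  shades, so realized frequencies are $f + (1-f)/6$ = 1/3, 1/2, 5/6.
* `genLettercolorSequence()` — 250 trials, 125 match (uniform over the 6
  associated pairs) and 125 no-match (uniform over the 30 others). A
  design cannot simultaneously balance match/no-match 1:1 *and* show all
  36 pairs equally often; we honor the 1:1 ratio, which is the constraint
  that defines the response options.
* `simulateBehavior()` — probability matching by default (the observer
  predicts each cue's majority outcome at the contingency rate), so
  expected accuracy approximates the frequency condition itself;
  log-normal RTs, slower on errors.
* `synthesizePupil()` — device-unit traces: constant level (5000 units)
  plus optional slow drift, one canonical impulse response
  $\mathrm{IRF}(t) \propto (t/t_{max})^{w} e^{w(1 - t/t_{max})}$
  (unit peak; $w = 10.1$, $t_{max} = 0.93$ s) per trial scaled by a
  planted amplitude $\beta_0 + \beta_I I + \beta_H H + \beta_{DKL} D_{KL}
  + \beta_{acc}(1 - \mathrm{accuracy})$ in percent-signal-change units,
  plus per-trial amplitude noise and white measurement noise; annotated
  blink dropouts at a configurable rate. The full ground truth is stored
  so recovery is checkable, and every generator is bit-reproducible from
  its seed.
* `genHlmTable()` — draws window-mean responses directly from the mixed
  model's own generative process (learner variables from simulated
  sequences, independent baseline/RT covariates, Gaussian subject
  intercepts). Parameter-recovery checks of the *model fit* use this
  table-level generator; trace-level planted effects go through
  `synthesizePupil()` and the full chain.

What the generators deliberately do **not** emulate: gaze-dependent
foreshortening, microsaccades, vendor file formats, the different
transient shapes of visual versus auditory feedback, non-stationary
arousal state, or participants whose learning deviates from the planted
loadings. Passing recovery tests therefore demonstrates that the
*pipeline* is correct and calibrated under its stated assumptions, not
that real recordings satisfy those assumptions.

# Numerical choices and problem sizes

* Window membership is half-open $[t_0, t_1)$ at sample resolution;
  onsets align to the nearest sample.
* A window-mean amplitude estimator has gain equal to the mean of the
  unit-peak IRF over the window (`irfWindowGain()`, about 0.89 for the
  early window); slope-recovery checks divide by it.
* The high-pass filter couples pre-trial baselines to the preceding
  response amplitudes (undershoot), so in trace-level simulations the
  baseline covariate is correlated with the planted amplitudes. This is
  a real property of the preprocessing, worth remembering when
  interpreting baseline coefficients; it is why model-fit recovery is
  assessed on model-generated tables.
* Simulation sizes were chosen once as the smallest that make the checks
  sharp: synthetic recordings run at 50 Hz (the band-pass and the IRF are
  fully resolved there), power and calibration use 24 simulated
  participants by 200 trials with 20 replicate seeds, the permutation
  null uses 500–1000 sign flips in simulations (10,000 by default in the
  pipeline), and the family-wise error simulation uses 500 null
  datasets.

# Known limitations

* The odd-ball prior's printed-probability normalization in the source
  literature could not be reconciled with the stated count model; the
  package asserts the ordering of the estimated prior mass across
  frequency conditions instead of absolute values.
* The mixed-model backend is maximum likelihood with cross-validated
  ELPD, not MCMC; interval coverage near variance boundaries (singular
  random-effect fits) inherits lme4's behavior.
* The cluster test assumes exchangeability of participant signs under
  the null (one-sample designs only; no between-group variant).
* Derivative-spike thresholds are device- and rate-dependent; the
  defaults are conventions, not calibrated constants.
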