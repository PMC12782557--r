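#' Synthetic task designs and pupil recordings
#'
#' Generators for the two associative-learning paradigms and for synthetic
#' pupil traces with planted loadings on the ideal-learner variables, so
#' that the learner, preprocessing and statistics modules can be exercised
#' end to end without recorded data. All generators are deterministic
#' given their seed.
#' @name synthetic
NULL

#' Generate a probabilistic cue-target 2AFC sequence
#'
#' Two cue shapes (square, diamond) each predict one target orientation
#' (left, right) on 80 percent of that cue's trials. The default
#' composition is exact-count: cues split 50/50 and within each cue the
#' 80/20 split holds by exact count, the order shuffled by seed. Events are
#' coded in the K = 4 cue x orientation space.
#'
#' @param nTrials number of trials (even; default 200).
#' @param mapping "condition1" (square -> left 80 percent) or "condition2"
#'   (mirror image).
#' @param contingency probability the cue's mapped orientation appears.
#' @param composition "exact" count composition or "iid" Bernoulli.
#' @param seed RNG seed.
#' @return data.frame: trial, cue (1 square / 2 diamond), orientation
#'   (1 left / 2 right), event (1..4 = (cue-1)*2 + orientation),
#'   frequency ("80" or "20" for congruent/incongruent trials).
#' @export
genCueTargetSequence <- function(nTrials = 200,
                                 mapping = c("condition1", "condition2"),
                                 contingency = 0.8,
                                 composition = c("exact", "iid"),
                                 seed = 1) {
  mapping <- match.arg(mapping)
  composition <- match.arg(composition)
  if (nTrials %% 2 != 0)
    stop("config error: nTrials must be even (cues split 50/50)")
  set.seed(seed)
  perCue <- nTrials / 2
  if (composition == "exact") {
    nCong <- round(contingency * perCue)
    if (abs(nCong - contingency * perCue) > 1e-9)
      stop("config error: contingency * nTrials/2 must be a whole number",
           " (remainder rounded)")
    cue <- rep(c(1L, 2L), each = perCue)
    congruent <- c(rep(c(TRUE, FALSE), c(nCong, perCue - nCong)),
                   rep(c(TRUE, FALSE), c(nCong, perCue - nCong)))
  } else {
    cue <- sample(rep(c(1L, 2L), each = perCue))
    congruent <- runif(nTrials) < contingency
  }
  mapped <- if (mapping == "condition1") c(1L, 2L) else c(2L, 1L)
  orientation <- ifelse(congruent, mapped[cue], 3L - mapped[cue])
  d <- data.frame(cue = cue, orientation = orientation,
                  frequency = ifelse(congruent, "80", "20"))
  if (composition == "exact") d <- d[sample(nrow(d)), ]
  d$trial <- seq_len(nTrials)
  d$event <- (d$cue - 1L) * 2L + d$orientation
  rownames(d) <- NULL
  d[, c("trial", "cue", "orientation", "event", "frequency")]
}

#' Generate an odd-ball exposure sequence
#'
#' 660 trials of which 60 are odd-balls; the 600 regular trials show the six
#' letters equally often. A letter assigned intended frequency f appears
#' with its associated color with probability f and otherwise with a color
#' drawn uniformly from all six shades, so the realized association
#' frequency is f + (1 - f)/6 (1/3, 1/2, 5/6 for f = 0.2, 0.4, 0.8). The
#' letter-to-color bijection and the letter-to-frequency assignment are
#' randomized by seed.
#'
#' @param nTrials total trials.
#' @param nOddballs number of odd-ball trials.
#' @param intendedFreq intended association frequencies, two letters each.
#' @param seed RNG seed.
#' @return list: \code{trials} data.frame (trial, is_oddball, letter,
#'   color, event = (letter-1)*6 + color, intended_freq, condition one of
#'   "33"/"50"/"84"; letter/color/event NA on odd-ball trials) and
#'   \code{assignment} data.frame (letter, color, intended_freq,
#'   condition).
#' @export
genOddballSequence <- function(nTrials = 660, nOddballs = 60,
                               intendedFreq = c(0.2, 0.2, 0.4, 0.4, 0.8, 0.8),
                               seed = 1) {
  set.seed(seed)
  nReg <- nTrials - nOddballs
  if (nReg %% 6 != 0)
    stop("config error: regular trials must divide evenly over 6 letters")
  assoc_color <- sample(6L)              # bijection letter -> color
  if (anyDuplicated(assoc_color)) stop("config error: duplicate assignment")
  freq <- sample(intendedFreq)           # letter -> intended frequency
  cond <- c("0.2" = "33", "0.4" = "50", "0.8" = "84")[as.character(freq)]
  letter <- sample(rep(1:6, each = nReg / 6))
  associated <- runif(nReg) < freq[letter]
  color <- ifelse(associated, assoc_color[letter],
                  sample(1:6, nReg, replace = TRUE))
  reg <- data.frame(is_oddball = FALSE, letter = letter, color = color,
                    intended_freq = freq[letter],
                    condition = cond[letter])
  odd <- data.frame(is_oddball = TRUE, letter = NA_integer_,
                    color = NA_integer_, intended_freq = NA_real_,
                    condition = NA_character_)
  trials <- rbind(reg, odd[rep(1, nOddballs), ])
  trials <- trials[sample(nrow(trials)), ]
  trials$trial <- seq_len(nTrials)
  trials$event <- (trials$letter - 1L) * 6L + trials$color
  rownames(trials) <- NULL
  list(trials = trials[, c("trial", "is_oddball", "letter", "color",
                           "event", "intended_freq", "condition")],
       assignment = data.frame(letter = 1:6, color = assoc_color,
                               intended_freq = freq, condition = cond))
}

#' Generate a letter-color 2AFC sequence
#'
#' 125 match trials (uniform over the six associated letter-color pairs)
#' and 125 no-match trials (uniform over the thirty unassociated pairs),
#' shuffled by seed, coded in the same K = 36 pair space as the prior.
#'
#' @param assignment the \code{assignment} table of
#'   \code{\link{genOddballSequence}}.
#' @param nTrials total trials (even).
#' @param seed RNG seed.
#' @return data.frame: trial, letter, color, event (1..36), match (0/1),
#'   condition (frequency condition of the trial's letter).
#' @export
genLettercolorSequence <- function(assignment, nTrials = 250, seed = 1) {
  if (!all(sort(assignment$letter) == 1:6) ||
      !all(sort(assignment$color) == 1:6))
    stop("config error: assignment must be a 6 x 6 bijection")
  if (nTrials %% 2 != 0) stop("config error: nTrials must be even")
  set.seed(seed)
  half <- nTrials / 2
  m_letter <- sample(1:6, half, replace = TRUE)
  m_color <- assignment$color[m_letter]
  nm_letter <- sample(1:6, half, replace = TRUE)
  nm_color <- vapply(nm_letter, function(l)
    sample(setdiff(1:6, assignment$color[l]), 1), 0L)
  d <- data.frame(letter = c(m_letter, nm_letter),
                  color = c(m_color, nm_color),
                  match = rep(c(1L, 0L), each = half))
  d <- d[sample(nrow(d)), ]
  d$trial <- seq_len(nTrials)
  d$event <- (d$letter - 1L) * 6L + d$color
  d$condition <- assignment$condition[d$letter]
  rownames(d) <- NULL
  d[, c("trial", "letter", "color", "event", "match", "condition")]
}

#' Simulate observer behavior
#'
#' Adds responses, accuracy and log-normal reaction times to a trial table.
#' Under probability matching on the cue-target design the observer
#' predicts each cue's majority orientation with the contingency
#' probability, so expected accuracy approximates the frequency condition
#' itself (0.8 and 0.2). \code{fixed_accuracy} draws accuracy Bernoulli(p)
#' on every trial.
#'
#' @param trials a trial table from a sequence generator.
#' @param policy "probability_matching" (needs cue/orientation columns) or
#'   "fixed_accuracy".
#' @param p accuracy under \code{fixed_accuracy}.
#' @param contingency cue-target contingency assumed by the matcher.
#' @param rtMeanlog,rtSdlog log-normal RT parameters.
#' @param rtErrorScale multiplicative RT slowing on error trials.
#' @param seed RNG seed.
#' @return the trial table plus columns accuracy (0/1) and rt (s).
#' @export
simulateBehavior <- function(trials,
                             policy = c("probability_matching",
                                        "fixed_accuracy"),
                             p = 0.8, contingency = 0.8,
                             rtMeanlog = log(0.7), rtSdlog = 0.25,
                             rtErrorScale = 1.3, seed = 1) {
  policy <- match.arg(policy)
  set.seed(seed)
  n <- nrow(trials)
  if (policy == "probability_matching") {
    if (!all(c("cue", "orientation") %in% names(trials)))
      stop("config error: probability matching needs cue/orientation")
    # majority orientation per cue, estimated from the sequence itself
    maj <- vapply(split(trials$orientation, trials$cue), function(o)
      as.integer(names(which.max(table(o)))), 0L)
    predict_maj <- runif(n) < contingency
    response <- ifelse(predict_maj, maj[as.character(trials$cue)],
                       3L - maj[as.character(trials$cue)])
    trials$accuracy <- as.integer(response == trials$orientation)
  } else {
    if (p < 0 || p > 1) stop("config error: p must lie in [0, 1]")
    trials$accuracy <- as.integer(runif(n) < p)
  }
  rt <- rlnorm(n, rtMeanlog, rtSdlog)
  trials$rt <- rt * ifelse(trials$accuracy == 1, 1, rtErrorScale)
  trials
}

#' Canonical pupil impulse response
#'
#' Erlang-shaped kernel (t / tmax)^w exp(w (1 - t / tmax)), normalized to
#' unit peak at \code{tmax}; zero for t <= 0.
#'
#' @param t time since event onset (s).
#' @param w shape parameter.
#' @param tmax time-to-peak (s).
#' @return kernel values, unit peak.
#' @export
pupilIrf <- function(t, w = 10.1, tmax = 0.93) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(w * (log(t[pos] / tmax) + 1 - t[pos] / tmax))
  out
}

#' Synthesize a pupil recording with planted effects
#'
#' Builds a device-unit trace as a constant level plus slow drift plus one
#' impulse response per trial scaled by a planted amplitude, plus white
#' measurement noise. The planted amplitude per trial (in percent-signal
#' -change units of the constant level) is
#' \code{beta0 + betaI I + betaH H + betaDKL DKL + betaAcc (1 - accuracy)}
#' plus Gaussian amplitude noise. Blink dropouts are injected at a
#' configurable rate and annotated. The ground truth needed for recovery
#' tests is returned alongside.
#'
#' @param trialInfo data.frame with columns I, H, DKL and optionally
#'   accuracy, one row per trial.
#' @param betas named list/vector: beta0, betaI, betaH, betaDKL, betaAcc
#'   (percent signal change per unit predictor; missing entries are 0).
#' @param fs sampling rate (Hz).
#' @param spacing_s onset-to-onset spacing (s, >= 3.5).
#' @param lead_s recording time before the first onset (s).
#' @param baselineLevel constant pupil level, device units.
#' @param amplitudeNoiseSd SD of per-trial amplitude noise (PSC units).
#' @param sampleNoiseSd SD of white measurement noise (device units).
#' @param driftAmp,driftPeriod_s slow sinusoidal drift (device units, s).
#' @param blinkRatePerMin expected blink dropouts per minute.
#' @param irfW,irfTmax impulse-response shape parameters.
#' @param seed RNG seed.
#' @return list: \code{recording} (\linkS4class{PupilRecording}),
#'   \code{annotations} (\linkS4class{ArtifactAnnotations}),
#'   \code{onsets_s} per-trial feedback onsets, \code{groundTruth} list
#'   (amplitudes in PSC units, betas, irf parameters, noise parameters,
#'   seed).
#' @export
synthesizePupil <- function(trialInfo, betas = list(beta0 = 1),
                            fs = 50, spacing_s = 6, lead_s = 4,
                            baselineLevel = 5000,
                            amplitudeNoiseSd = 0, sampleNoiseSd = 0,
                            driftAmp = 0, driftPeriod_s = 120,
                            blinkRatePerMin = 0,
                            irfW = 10.1, irfTmax = 0.93, seed = 1) {
  if (spacing_s < 3.5) stop("scheduling error: spacing must be >= 3.5 s")
  set.seed(seed)
  b <- function(nm) if (!is.null(betas[[nm]])) betas[[nm]] else 0
  n_tr <- nrow(trialInfo)
  err <- if ("accuracy" %in% names(trialInfo)) 1 - trialInfo$accuracy else 0
  amp_psc <- b("beta0") + b("betaI") * trialInfo$I +
    b("betaH") * trialInfo$H + b("betaDKL") * trialInfo$DKL +
    b("betaAcc") * err +
    rnorm(n_tr, 0, amplitudeNoiseSd)
  onsets <- lead_s + (seq_len(n_tr) - 1) * spacing_s
  dur <- onsets[n_tr] + spacing_s
  nS <- round(dur * fs)
  tt <- (seq_len(nS) - 1) / fs
  if (onsets[1] < 0.5 || onsets[n_tr] + 3 > tt[nS])
    stop("scheduling error: onsets too close to recording edges")
  kernel <- pupilIrf(seq(0, 4, by = 1 / fs), w = irfW, tmax = irfTmax)
  y <- rep(baselineLevel, nS) +
    driftAmp * sin(2 * pi * tt / driftPeriod_s)
  for (i in seq_len(n_tr)) {
    i0 <- round(onsets[i] * fs) + 1
    idx <- i0:min(i0 + length(kernel) - 1, nS)
    y[idx] <- y[idx] + (amp_psc[i] / 100 * baselineLevel) *
      kernel[seq_along(idx)]
  }
  if (sampleNoiseSd > 0) y <- y + rnorm(nS, 0, sampleNoiseSd)
  # blink dropouts
  nBlink <- rpois(1, blinkRatePerMin * dur / 60)
  kind <- character(); st <- numeric(); en <- numeric()
  if (nBlink > 0) {
    bt <- sort(runif(nBlink, 1, dur - 1))
    for (t0 in bt) {
      i0 <- round(t0 * fs) + 1
      i1 <- min(i0 + round(0.1 * fs), nS)
      y[i0:i1] <- 0
      kind <- c(kind, "blink"); st <- c(st, t0); en <- c(en, t0 + 0.1)
    }
  }
  rec <- PupilRecording(y, fs = fs)
  list(recording = rec,
       annotations = ArtifactAnnotations(kind, st, en),
       onsets_s = onsets,
       groundTruth = list(amplitudes_psc = amp_psc, betas = betas,
                          irf = c(w = irfW, tmax = irfTmax),
                          baselineLevel = baselineLevel,
                          amplitudeNoiseSd = amplitudeNoiseSd,
                          sampleNoiseSd = sampleNoiseSd,
                          blinkRatePerMin = blinkRatePerMin, seed = seed))
}

#' Mean of the unit-peak impulse response over a window
#'
#' The gain of a window-mean amplitude estimator: a response of planted
#' amplitude a contributes a times this value to the mean over the window,
#' so dividing window means by it calibrates slope-recovery checks.
#'
#' @param window c(start, end) seconds after onset.
#' @param fs sampling rate used for the numerical mean.
#' @param w,tmax kernel parameters.
#' @return scalar gain in (0, 1].
#' @export
irfWindowGain <- function(window, fs = 500, w = 10.1, tmax = 0.93) {
  tt <- seq(window[1], window[2] - 1 / fs, by = 1 / fs)
  mean(pupilIrf(tt, w = w, tmax = tmax))
}

#' Generate trial tables from the mixed model's own generative process
#'
#' Draws window-mean pupil values directly from the random-intercept
#' regression model: learner variables from simulated cue-target
#' sequences, independent baseline and RT covariates, a Gaussian subject
#' intercept and residual noise. Used for parameter-recovery checks of
#' the model fit itself (the trace-level pipeline has its own planted
#' -amplitude checks).
#'
#' @param nSubjects,nTrials design size.
#' @param betas named vector/list: beta0, betaI, betaH, betaDKL,
#'   betaBaseline, betaRt, betaHxDKL (missing entries are 0).
#' @param sdSubject SD of the subject random intercept.
#' @param sigma residual SD.
#' @param seed RNG seed.
#' @return data.frame: pupil, I, H, DKL, baseline, rt, subject.
#' @export
genHlmTable <- function(nSubjects = 24, nTrials = 200,
                        betas = list(beta0 = 0, betaDKL = 50),
                        sdSubject = 2, sigma = 4, seed = 1) {
  b <- function(nm) if (!is.null(betas[[nm]])) betas[[nm]] else 0
  rows <- lapply(seq_len(nSubjects), function(s) {
    seq_seed <- seed * 10000L + s
    trials <- genCueTargetSequence(nTrials, seed = seq_seed)
    info <- runLearner(trials$event, uniformPrior(4))
    set.seed(seq_seed + 1L)
    baseline <- rnorm(nTrials, 0, 2)
    rt <- rlnorm(nTrials, log(0.7), 0.25)
    u <- rnorm(1, 0, sdSubject)
    pupil <- b("beta0") + b("betaI") * info$I + b("betaH") * info$H +
      b("betaDKL") * info$DKL + b("betaBaseline") * baseline +
      b("betaRt") * rt + b("betaHxDKL") * info$H * info$DKL +
      u + rnorm(nTrials, 0, sigma)
    data.frame(pupil = pupil, I = info$I, H = info$H, DKL = info$DKL,
               baseline = baseline, rt = rt, subject = s)
  })
  do.call(rbind, rows)
}
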