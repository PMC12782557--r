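#' @import methods
NULL

TOL_PROB <- 1e-9

#' Dirichlet prior specification
#'
#' Holds the concentration vector of a Dirichlet prior over K discrete event
#' types, together with its provenance. Priors are either uniform or
#' estimated from the final event probabilities of an odd-ball exposure
#' phase. When \code{scaleMode} is \code{"pseudo_counts_sum_K"} a raw
#' probability vector \code{Po} is rescaled so the concentrations sum to K
#' (one pseudo-count per event type overall); with \code{"raw_probabilities"}
#' the probabilities themselves are used as concentrations.
#'
#' @slot alpha numeric vector of K positive concentration parameters.
#' @slot source character, \code{"uniform"} or \code{"oddball_estimated"}.
#' @slot Po numeric, the probability vector the prior was derived from
#'   (length K, sums to 1), or \code{numeric(0)} for uniform priors.
#' @slot scaleMode character, \code{"pseudo_counts_sum_K"} or
#'   \code{"raw_probabilities"}.
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(alpha = "numeric", source = "character",
                 Po = "numeric", scaleMode = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@alpha) < 2L) msg <- c(msg, "alpha must have length >= 2")
    if (any(!is.finite(object@alpha)) || any(object@alpha <= 0))
      msg <- c(msg, "all alpha must be positive and finite")
    if (!object@source %in% c("uniform", "oddball_estimated"))
      msg <- c(msg, "source must be 'uniform' or 'oddball_estimated'")
    if (!object@scaleMode %in% c("pseudo_counts_sum_K", "raw_probabilities"))
      msg <- c(msg, "invalid scaleMode")
    if (length(object@Po)) {
      if (length(object@Po) != length(object@alpha))
        msg <- c(msg, "Po must match alpha in length")
      if (any(object@Po <= 0)) msg <- c(msg, "all Po entries must be > 0")
      if (abs(sum(object@Po) - 1) > TOL_PROB)
        msg <- c(msg, "Po must sum to 1")
    }
    if (object@scaleMode == "pseudo_counts_sum_K" &&
        abs(sum(object@alpha) - length(object@alpha)) > 1e-6)
      msg <- c(msg, "alpha must sum to K under pseudo_counts_sum_K")
    if (length(msg)) msg else TRUE
  })

#' Belief state of the Dirichlet-categorical ideal observer
#'
#' The observer's state after absorbing \code{j} events: the fixed prior
#' concentrations plus the per-type event counts. The posterior over the
#' event probability vector is Dirichlet with concentration
#' \code{alpha + counts}; its mean is returned by \code{\link{posteriorMean}}.
#'
#' @slot alpha numeric, prior concentration vector (K positive values).
#' @slot counts integer, per-type event counts, non-negative.
#' @slot j integer, number of observations absorbed (equals sum(counts)).
#' @exportClass BeliefState
setClass("BeliefState",
  representation(alpha = "numeric", counts = "integer", j = "integer"),
  validity = function(object) {
    msg <- character()
    K <- length(object@alpha)
    if (K < 2L) msg <- c(msg, "K must be >= 2")
    if (any(object@alpha <= 0)) msg <- c(msg, "alpha must be positive")
    if (length(object@counts) != K) msg <- c(msg, "counts length must equal K")
    if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
    if (sum(object@counts) != object@j) msg <- c(msg, "sum(counts) must equal j")
    pm <- (object@counts + object@alpha) / (object@j + sum(object@alpha))
    if (abs(sum(pm) - 1) > TOL_PROB)
      msg <- c(msg, "posterior mean must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Uniformly sampled pupil recording
#'
#' A pupil-size time series on a uniform time grid with a per-sample
#' validity mask and a record of which preprocessing stages have been
#' applied.
#'
#' @slot t numeric, sample times in seconds, strictly increasing, uniform.
#' @slot y numeric, pupil size (device units or percent signal change).
#' @slot fs numeric, sampling rate in Hz.
#' @slot valid logical, per-sample validity.
#' @slot stage character, ordered names of applied processing steps.
#' @exportClass PupilRecording
setClass("PupilRecording",
  representation(t = "numeric", y = "numeric", fs = "numeric",
                 valid = "logical", stage = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@t)
    if (length(object@y) != n || length(object@valid) != n)
      msg <- c(msg, "t, y and valid must have equal length")
    if (n >= 2) {
      dt <- diff(object@t)
      if (any(dt <= 0)) msg <- c(msg, "t must be strictly increasing")
      step <- 1 / object@fs
      if (max(abs(dt - step)) > 1e-9 * max(1, step))
        msg <- c(msg, "sampling must be uniform at 1/fs")
    }
    if (object@fs <= 0) msg <- c(msg, "fs must be positive")
    if (length(msg)) msg else TRUE
  })

#' Artifact interval annotations
#'
#' Intervals of a recording affected by missing samples, blinks, saccades or
#' derivative spikes, in seconds.
#'
#' @slot intervals data.frame with columns kind (character), start_s, end_s.
#' @exportClass ArtifactAnnotations
setClass("ArtifactAnnotations",
  representation(intervals = "data.frame"),
  validity = function(object) {
    iv <- object@intervals
    msg <- character()
    need <- c("kind", "start_s", "end_s")
    if (!all(need %in% names(iv)))
      msg <- c(msg, "intervals needs columns kind, start_s, end_s")
    else if (nrow(iv) && any(iv$start_s >= iv$end_s))
      msg <- c(msg, "start_s must be < end_s")
    if (length(msg)) msg else TRUE
  })

#' Feedback-locked epochs
#'
#' A trials x timepoints matrix of pupil values locked to feedback onset,
#' with the relative time axis, per-trial pre-feedback baselines and a
#' per-trial label table (subject, condition, accuracy, RT, ...).
#'
#' @slot data numeric matrix, trials x timepoints.
#' @slot time numeric, seconds relative to feedback onset, one per column.
#' @slot baselines numeric, per-trial baseline mean (NA until baselining).
#' @slot labels data.frame, one row per trial.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "matrix", time = "numeric",
                 baselines = "numeric", labels = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@data) != length(object@time))
      msg <- c(msg, "time length must equal ncol(data)")
    if (nrow(object@data) != nrow(object@labels))
      msg <- c(msg, "labels rows must align with data rows")
    if (length(object@baselines) &&
        length(object@baselines) != nrow(object@data))
      msg <- c(msg, "baselines must be one per trial")
    if (length(msg)) msg else TRUE
  })

#' Fisher-z correlation time course
#'
#' Per-participant Fisher-transformed trial-wise correlations between a
#' model variable and the pupil value at each epoch timepoint.
#'
#' @slot z numeric matrix, participants x timepoints; rows may be all-NA
#'   for participants excluded by zero-variance regressors.
#' @slot variable character, name of the model variable (e.g. "DKL").
#' @slot time numeric, seconds relative to feedback onset.
#' @slot subset character, "all", "correct" or "error".
#' @exportClass CorrTimecourse
setClass("CorrTimecourse",
  representation(z = "matrix", variable = "character",
                 time = "numeric", subset = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@z) != length(object@time))
      msg <- c(msg, "time length must equal ncol(z)")
    if (!object@subset %in% c("all", "correct", "error"))
      msg <- c(msg, "subset must be all/correct/error")
    if (length(msg)) msg else TRUE
  })

# ---- constructors ----

#' Create a pupil recording
#'
#' @param y numeric pupil samples.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (s).
#' @param valid logical validity mask (default all valid).
#' @param stage character vector of applied stages.
#' @return A \linkS4class{PupilRecording}.
#' @export
PupilRecording <- function(y, fs, t0 = 0, valid = rep(TRUE, length(y)),
                           stage = "raw") {
  new("PupilRecording", t = t0 + (seq_along(y) - 1) / fs,
      y = as.numeric(y), fs = fs, valid = valid, stage = stage)
}

#' Create artifact annotations
#'
#' @param kind character vector of artifact kinds.
#' @param start_s,end_s interval bounds in seconds.
#' @return An \linkS4class{ArtifactAnnotations}.
#' @export
ArtifactAnnotations <- function(kind = character(), start_s = numeric(),
                                end_s = numeric()) {
  new("ArtifactAnnotations",
      intervals = data.frame(kind = as.character(kind),
                             start_s = as.numeric(start_s),
                             end_s = as.numeric(end_s)))
}

# ---- accessors ----

#' @describeIn PupilRecording-class sample times (s)
#' @param object,x a PupilRecording
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @export
setMethod("sampleTimes", "PupilRecording", function(object) object@t)

#' @export
setGeneric("pupilSize", function(object) standardGeneric("pupilSize"))
#' @describeIn PupilRecording-class pupil sample values
#' @export
setMethod("pupilSize", "PupilRecording", function(object) object@y)

#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @describeIn PupilRecording-class sampling rate in Hz
#' @export
setMethod("samplingRate", "PupilRecording", function(object) object@fs)

#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @describeIn PupilRecording-class per-sample validity
#' @export
setMethod("validMask", "PupilRecording", function(object) object@valid)

#' @export
setGeneric("artifactIntervals",
           function(object) standardGeneric("artifactIntervals"))
#' @describeIn ArtifactAnnotations-class interval table
#' @param object an ArtifactAnnotations
#' @export
setMethod("artifactIntervals", "ArtifactAnnotations",
          function(object) object@intervals)

#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @describeIn EpochSet-class trials x timepoints matrix
#' @param object an EpochSet
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)

#' @export
setGeneric("epochTime", function(object) standardGeneric("epochTime"))
#' @describeIn EpochSet-class relative time axis (s)
#' @export
setMethod("epochTime", "EpochSet", function(object) object@time)

#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))
#' @describeIn EpochSet-class per-trial label table
#' @export
setMethod("epochLabels", "EpochSet", function(object) object@labels)

#' @export
setGeneric("epochBaselines", function(object) standardGeneric("epochBaselines"))
#' @describeIn EpochSet-class per-trial baseline means
#' @export
setMethod("epochBaselines", "EpochSet", function(object) object@baselines)

#' @export
setGeneric("fisherZ", function(object) standardGeneric("fisherZ"))
#' @describeIn CorrTimecourse-class participants x timepoints Fisher-z matrix
#' @param object a CorrTimecourse
#' @export
setMethod("fisherZ", "CorrTimecourse", function(object) object@z)

#' Number of observations absorbed by a belief state
#' @param object a BeliefState
#' @export
setGeneric("nObserved", function(object) standardGeneric("nObserved"))
#' @describeIn BeliefState-class trials absorbed so far
#' @export
setMethod("nObserved", "BeliefState", function(object) object@j)

#' @export
setGeneric("eventCounts", function(object) standardGeneric("eventCounts"))
#' @describeIn BeliefState-class per-type event counts
#' @export
setMethod("eventCounts", "BeliefState", function(object) object@counts)

#' @export
setGeneric("priorAlpha", function(object) standardGeneric("priorAlpha"))
#' @describeIn BeliefState-class prior concentration vector
#' @export
setMethod("priorAlpha", "BeliefState", function(object) object@alpha)
#' @describeIn PriorSpec-class concentration vector after scale resolution
#' @export
setMethod("priorAlpha", "PriorSpec", function(object) object@alpha)

# ---- show methods ----

setMethod("show", "BeliefState", function(object) {
  cat("BeliefState: K =", length(object@alpha), ", j =", object@j, "\n")
  cat("  alpha:", paste(signif(object@alpha, 4), collapse = " "), "\n")
  cat("  counts:", paste(object@counts, collapse = " "), "\n")
})

setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec (", object@source, ", ", object@scaleMode, "): K = ",
      length(object@alpha), "\n", sep = "")
})

setMethod("show", "PupilRecording", function(object) {
  cat("PupilRecording:", length(object@y), "samples @", object@fs, "Hz (",
      signif(diff(range(object@t)), 5), "s ), stage:",
      paste(object@stage, collapse = " -> "), "\n")
  cat("  invalid samples:", sum(!object@valid), "\n")
})

setMethod("show", "ArtifactAnnotations", function(object) {
  cat("ArtifactAnnotations:", nrow(object@intervals), "intervals\n")
  if (nrow(object@intervals))
    print(table(object@intervals$kind))
})

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet:", nrow(object@data), "trials x", ncol(object@data),
      "timepoints, t in [", min(object@time), ",", max(object@time), "] s\n")
  cat("  baselined:", length(object@baselines) > 0, "\n")
})

setMethod("show", "CorrTimecourse", function(object) {
  cat("CorrTimecourse(", object@variable, ", subset=", object@subset, "): ",
      nrow(object@z), " participants x ", ncol(object@z), " timepoints\n",
      sep = "")
})
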