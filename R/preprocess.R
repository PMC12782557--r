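#' Pupil preprocessing chain
#'
#' The standard chain applied to a raw pupil trace before epoching:
#' (i) padded linear interpolation across missing samples, (ii) the same
#' across blink/saccade intervals found as spikes in the first derivative,
#' (iii) zero-phase third-order Butterworth band-pass (0.01-6 Hz),
#' (iv) FIR deconvolution of blink and saccade responses removed by linear
#' regression, and (v) conversion of the residuals to percent signal change
#' with respect to the temporal mean of the pre-filter signal.
#' @name preprocess
NULL

merge_intervals <- function(start, end) {
  if (!length(start)) return(cbind(start = numeric(), end = numeric()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Detect blink/saccade artifacts from the first derivative
#'
#' Flags samples whose absolute first difference exceeds a threshold rate of
#' change and merges adjacent flagged samples into intervals. The default
#' threshold of 10 units per sample follows common practice for raw
#' device-unit traces and is device dependent.
#'
#' @param rec a \linkS4class{PupilRecording}.
#' @param threshold absolute first difference, units per sample.
#' @return An \linkS4class{ArtifactAnnotations} with kind
#'   "derivative_spike".
#' @export
detectDerivativeArtifacts <- function(rec, threshold = 10) {
  stopifnot(is(rec, "PupilRecording"))
  d <- abs(diff(rec@y))
  hit <- which(d > threshold)
  if (!length(hit))
    return(ArtifactAnnotations())
  # a spike in the difference between samples i and i+1 taints both
  runs <- split(hit, cumsum(c(1, diff(hit) > 1)))
  dt <- 1 / rec@fs
  start_s <- vapply(runs, function(r) rec@t[r[1]], 0)
  end_s <- vapply(runs, function(r) rec@t[r[length(r)] + 1] + dt / 2, 0)
  ArtifactAnnotations(kind = rep("derivative_spike", length(runs)),
                      start_s = start_s, end_s = end_s)
}

#' Interpolate across artifact intervals
#'
#' Each interval is expanded by \code{pad_s} on both sides (clamped to the
#' recording, overlaps merged) and the samples inside are replaced by linear
#' interpolation between the nearest untouched boundary samples. Gaps
#' reaching the recording edge are filled with the nearest retained value.
#' Samples outside padded intervals are untouched.
#'
#' @param rec a \linkS4class{PupilRecording}.
#' @param annotations an \linkS4class{ArtifactAnnotations}.
#' @param pad_s padding in seconds applied before and after each interval.
#' @return The interpolated \linkS4class{PupilRecording} (mask set valid).
#' @export
interpolateIntervals <- function(rec, annotations, pad_s = 0.15) {
  stopifnot(is(rec, "PupilRecording"))
  iv <- artifactIntervals(annotations)
  bad <- !rec@valid
  if (nrow(iv)) {
    m <- merge_intervals(pmax(iv$start_s - pad_s, rec@t[1]),
                         pmin(iv$end_s + pad_s, rec@t[length(rec@t)]))
    for (i in seq_len(nrow(m)))
      bad <- bad | (rec@t >= m[i, 1] & rec@t <= m[i, 2])
  } else if (any(bad)) {
    # pad around invalid-sample runs too
    runs <- split(which(bad), cumsum(c(1, diff(which(bad)) > 1)))
    for (r in runs) {
      lo <- rec@t[r[1]] - pad_s; hi <- rec@t[r[length(r)]] + pad_s
      bad <- bad | (rec@t >= lo & rec@t <= hi)
    }
  }
  if (!any(bad)) {
    out <- rec
    out@stage <- c(rec@stage, "interpolated")
    return(out)
  }
  if (all(bad)) stop("unrecoverable recording: no valid samples")
  y <- rec@y
  idx_ok <- which(!bad)
  y[bad] <- approx(x = rec@t[idx_ok], y = y[idx_ok], xout = rec@t[bad],
                   rule = 2)$y
  new("PupilRecording", t = rec@t, y = y, fs = rec@fs,
      valid = rep(TRUE, length(y)), stage = c(rec@stage, "interpolated"))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order Butterworth high-pass and low-pass sections applied
#' forward-backward (zero phase, no latency shift of feedback-locked
#' responses). The DC component is removed by the high-pass.
#'
#' @param rec a \linkS4class{PupilRecording}.
#' @param low,high band edges in Hz.
#' @param order filter order of each section.
#' @return The filtered \linkS4class{PupilRecording}, mean approximately 0.
#' @export
bandpassFilter <- function(rec, low = 0.01, high = 6, order = 3) {
  stopifnot(is(rec, "PupilRecording"))
  nyq <- rec@fs / 2
  if (high >= nyq) stop("invalid filter: high cutoff must be < Nyquist")
  if (low <= 0 || low >= high) stop("invalid filter: need 0 < low < high")
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  y <- rec@y - mean(rec@y)  # pre-demean keeps filtfilt transients tiny
  y <- signal::filtfilt(hp, y)
  y <- signal::filtfilt(lp, y)
  new("PupilRecording", t = rec@t, y = y, fs = rec@fs, valid = rec@valid,
      stage = c(rec@stage, "bandpassed"))
}

# linear-interpolation (hat function) FIR basis: coefficient b is the
# kernel value at lag (b-1)/res_hz, interpolated linearly back to fs
fir_design_matrix <- function(n, fs, onsets_s, t0, dur_s, res_hz) {
  n_basis <- round(dur_s * res_hz) + 1
  X <- matrix(0, n, n_basis)
  lag_max <- dur_s
  nlag <- round(lag_max * fs)
  for (on in onsets_s) {
    i0 <- round((on - t0) * fs) + 1
    idx <- i0:(i0 + nlag)
    inb <- idx >= 1 & idx <= n
    if (!any(inb)) next
    lag_s <- (idx[inb] - i0) / fs
    pos <- lag_s * res_hz + 1          # fractional basis position
    b_lo <- pmin(floor(pos), n_basis)
    frac <- pos - b_lo
    rows <- idx[inb]
    for (r in seq_along(rows)) {
      X[rows[r], b_lo[r]] <- X[rows[r], b_lo[r]] + (1 - frac[r])
      if (b_lo[r] < n_basis && frac[r] > 0)
        X[rows[r], b_lo[r] + 1] <- X[rows[r], b_lo[r] + 1] + frac[r]
    }
  }
  X
}

#' Remove deconvolved nuisance responses
#'
#' For each nuisance kind (blink, saccade) a finite impulse response over
#' [0, dur_s] seconds is estimated by ordinary least squares from an event-locked
#' linear-interpolation FIR basis at \code{res_hz} resolution; the fitted nuisance
#' signal is subtracted from the trace. Event time is the end of each
#' artifact interval (when the eye reopens / the gaze lands).
#'
#' @param rec a filtered \linkS4class{PupilRecording}.
#' @param annotations \linkS4class{ArtifactAnnotations}; kinds "blink" and
#'   "saccade" are used (others ignored).
#' @param dur_s FIR duration in seconds.
#' @param res_hz FIR design resolution in Hz.
#' @return list with the residual \code{recording} and per-kind estimated
#'   kernels \code{irf} (named list of data.frames with lag_s, coef).
#' @export
removeNuisanceResponses <- function(rec, annotations, dur_s = 6,
                                    res_hz = 20) {
  stopifnot(is(rec, "PupilRecording"))
  iv <- artifactIntervals(annotations)
  kinds <- intersect(c("blink", "saccade"), unique(iv$kind))
  out <- rec
  out@stage <- c(rec@stage, "nuisance_regressed")
  if (!length(kinds))
    return(list(recording = out, irf = list()))
  n <- length(rec@y)
  Xs <- lapply(kinds, function(kd)
    fir_design_matrix(n, rec@fs, iv$end_s[iv$kind == kd], rec@t[1],
                      dur_s, res_hz))
  X <- do.call(cbind, Xs)
  if (ncol(X) >= n) stop("underdetermined design: more FIR coefficients than samples")
  keep <- colSums(abs(X)) > 0
  beta <- numeric(ncol(X))
  if (any(keep)) {
    fit <- lm.fit(X[, keep, drop = FALSE], rec@y)
    beta[keep] <- fit$coefficients
    beta[is.na(beta)] <- 0
  }
  fitted <- as.vector(X %*% beta)
  out@y <- rec@y - fitted
  n_basis <- round(dur_s * res_hz) + 1
  irf <- list()
  for (i in seq_along(kinds)) {
    b <- beta[((i - 1) * n_basis + 1):(i * n_basis)]
    irf[[kinds[i]]] <- data.frame(lag_s = (seq_len(n_basis) - 1) / res_hz,
                                  coef = b)
  }
  list(recording = out, irf = irf)
}

#' Convert to percent signal change
#'
#' @param rec a \linkS4class{PupilRecording} of nuisance residuals.
#' @param referenceMean temporal mean of the pre-filter signal (> 0).
#' @return The rescaled \linkS4class{PupilRecording}, units percent.
#' @export
percentSignalChange <- function(rec, referenceMean) {
  stopifnot(is(rec, "PupilRecording"))
  if (!is.finite(referenceMean) || referenceMean <= 0)
    stop("invalid reference: referenceMean must be > 0")
  out <- rec
  out@y <- 100 * rec@y / referenceMean
  out@stage <- c(rec@stage, "psc")
  out
}

#' Full preprocessing chain
#'
#' Runs interpolation (missing samples, then derivative-detected spikes),
#' band-pass filtering, nuisance deconvolution and percent-signal-change
#' scaling in order. The percent-signal-change reference is the temporal
#' mean of the interpolated (pre-filter) trace.
#'
#' @param rec a raw \linkS4class{PupilRecording}.
#' @param annotations known artifact intervals (missing/blink/saccade).
#' @param derivThreshold first-difference threshold, units per sample.
#' @param pad_s interpolation padding (s).
#' @param band band-pass edges in Hz.
#' @param filterOrder Butterworth section order.
#' @param deconvDur_s,deconvRes_hz FIR window and design resolution.
#' @return list: \code{recording} (percent signal change), \code{irf}
#'   (estimated nuisance kernels), \code{referenceMean},
#'   \code{annotations} (input plus derivative spikes).
#' @export
preprocessPupil <- function(rec, annotations = ArtifactAnnotations(),
                            derivThreshold = 10, pad_s = 0.15,
                            band = c(0.01, 6), filterOrder = 3,
                            deconvDur_s = 6, deconvRes_hz = 20) {
  r1 <- interpolateIntervals(rec, annotations, pad_s = pad_s)
  spikes <- detectDerivativeArtifacts(r1, threshold = derivThreshold)
  if (nrow(artifactIntervals(spikes)))
    r1 <- interpolateIntervals(r1, spikes, pad_s = pad_s)
  refMean <- mean(r1@y)
  r2 <- bandpassFilter(r1, low = band[1], high = band[2],
                       order = filterOrder)
  iv <- rbind(artifactIntervals(annotations), artifactIntervals(spikes))
  nr <- removeNuisanceResponses(r2, new("ArtifactAnnotations",
                                        intervals = iv),
                                dur_s = deconvDur_s, res_hz = deconvRes_hz)
  r3 <- percentSignalChange(nr$recording, refMean)
  list(recording = r3, irf = nr$irf, referenceMean = refMean,
       annotations = new("ArtifactAnnotations", intervals = iv))
}
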