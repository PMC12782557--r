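#' Extract feedback-locked epochs
#'
#' Cuts one row per feedback onset from a recording, on a relative time
#' axis covering \code{window}. The sample at relative time t is the
#' recorded sample nearest to onset + t. Onsets whose window falls outside
#' the recording are dropped with a warning naming the trials.
#'
#' @param rec a preprocessed \linkS4class{PupilRecording}.
#' @param onsets_s feedback onset times in seconds.
#' @param window c(start, end) relative to onset, seconds.
#' @param labels data.frame with one row per onset (condition, subject,
#'   accuracy, rt, ...); dropped trials lose their rows too.
#' @return An \linkS4class{EpochSet} (not yet baseline corrected).
#' @export
extractEpochs <- function(rec, onsets_s, window = c(-0.5, 3.0),
                          labels = data.frame(trial = seq_along(onsets_s))) {
  stopifnot(is(rec, "PupilRecording"))
  if (nrow(labels) != length(onsets_s))
    stop("labels must have one row per onset")
  fs <- rec@fs
  rel <- seq(window[1], window[2], by = 1 / fs)
  n <- length(rec@y)
  rows <- vector("list", length(onsets_s))
  ok <- logical(length(onsets_s))
  for (i in seq_along(onsets_s)) {
    idx <- round((onsets_s[i] + rel - rec@t[1]) * fs) + 1
    if (idx[1] < 1 || idx[length(idx)] > n) next
    rows[[i]] <- rec@y[idx]
    ok[i] <- TRUE
  }
  if (!all(ok))
    warning("dropped out-of-bounds trials: ",
            paste(which(!ok), collapse = ", "))
  if (!any(ok)) stop("no onsets fit inside the recording")
  new("EpochSet", data = do.call(rbind, rows[ok]), time = rel,
      baselines = numeric(), labels = labels[ok, , drop = FALSE])
}

window_mask <- function(time, w) time >= w[1] & time < w[2]

#' Baseline-correct epochs and summarise analysis windows
#'
#' Subtracts the per-trial mean over the pre-feedback baseline window from
#' the whole epoch, then averages the corrected trace over each half-open
#' analysis window.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param baseline c(start, end) of the baseline window (s, half-open).
#' @param windows named list of analysis windows, each c(start, end).
#' @return list: \code{epochs}, the corrected \linkS4class{EpochSet} with
#'   baselines filled in; \code{table}, a data.frame of the labels plus
#'   baseline and one column per window.
#' @export
baselineAndWindow <- function(epochs,
                              baseline = c(-0.5, 0),
                              windows = list(early = c(0.75, 1.25),
                                             late = c(2.5, 3.0))) {
  stopifnot(is(epochs, "EpochSet"))
  tm <- epochs@time
  bm <- window_mask(tm, baseline)
  if (!any(bm)) stop("invalid window: baseline outside epoch span")
  for (w in windows)
    if (!any(window_mask(tm, w)))
      stop("invalid window: analysis window outside epoch span")
  base <- rowMeans(epochs@data[, bm, drop = FALSE])
  corrected <- epochs@data - base
  out <- epochs
  out@data <- corrected
  out@baselines <- base
  tab <- epochs@labels
  tab$baseline <- base
  for (nm in names(windows)) {
    wm <- window_mask(tm, windows[[nm]])
    tab[[nm]] <- rowMeans(corrected[, wm, drop = FALSE])
  }
  list(epochs = out, table = tab)
}

#' Reaction-time outlier exclusion
#'
#' Z-scores each participant's RTs and excludes trials with |z| above the
#' criterion. Degenerate (zero-variance) RT distributions exclude nothing.
#'
#' @param rt numeric reaction times (s), missed responses already removed.
#' @param subject participant id per trial (single participant if missing).
#' @param zCrit exclusion criterion on |z|.
#' @return list: \code{keep} logical mask, \code{excludedFraction}.
#' @export
excludeRtOutliers <- function(rt, subject = rep(1L, length(rt)), zCrit = 3) {
  stopifnot(length(rt) == length(subject))
  keep <- rep(TRUE, length(rt))
  for (s in unique(subject)) {
    i <- which(subject == s)
    if (length(i) < 2) next
    sdv <- sd(rt[i])
    if (!is.finite(sdv) || sdv == 0) {
      warning("zero RT variance for subject ", s, "; no exclusions")
      next
    }
    z <- (rt[i] - mean(rt[i])) / sdv
    keep[i] <- abs(z) <= zCrit
  }
  list(keep = keep, excludedFraction = mean(!keep))
}
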