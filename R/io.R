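#' Delimited-text readers and writers
#'
#' All on-disk formats are plain TSV (plus a JSON sidecar for the epoch
#' time axis) so that runs are inspectable and diffable.
#' @name io
NULL

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read an events table
#'
#' Expects at least columns subject, trial, event; optional is_oddball,
#' condition columns, feedback_onset_s, rt_s, accuracy.
#' @param path TSV path.
#' @return data.frame.
#' @export
readEventsTable <- function(path) {
  d <- read_tsv(path)
  need <- c("subject", "trial", "event")
  if (!all(need %in% names(d)))
    stop("events table needs columns: ", paste(need, collapse = ", "))
  d
}

#' Write per-trial learner output
#' @param trialInfo data.frame from \code{\link{runLearner}} (plus an
#'   optional subject column).
#' @param path TSV path.
#' @export
writeTrialInfo <- function(trialInfo, path) write_tsv(trialInfo, path)

#' Read pupil samples (columns t_s, pupil, valid)
#' @param path TSV path.
#' @return A \linkS4class{PupilRecording}.
#' @export
readPupilSamples <- function(path) {
  d <- read_tsv(path)
  need <- c("t_s", "pupil", "valid")
  if (!all(need %in% names(d)))
    stop("samples table needs columns: ", paste(need, collapse = ", "))
  fs <- 1 / stats::median(diff(d$t_s))
  new("PupilRecording", t = d$t_s, y = d$pupil, fs = fs,
      valid = as.logical(d$valid), stage = "raw")
}

#' Write pupil samples
#' @param rec a \linkS4class{PupilRecording}.
#' @param path TSV path.
#' @export
writePupilSamples <- function(rec, path) {
  write_tsv(data.frame(t_s = rec@t, pupil = rec@y,
                       valid = as.integer(rec@valid)), path)
}

#' Read artifact intervals (columns kind, start_s, end_s)
#' @param path TSV path.
#' @return An \linkS4class{ArtifactAnnotations}.
#' @export
readArtifacts <- function(path) {
  d <- read_tsv(path)
  ArtifactAnnotations(d$kind, d$start_s, d$end_s)
}

#' Write epochs as a delimited matrix plus JSON time-axis sidecar
#' @param epochs an \linkS4class{EpochSet}.
#' @param path TSV path; the sidecar is written to paste0(path, ".json").
#' @export
writeEpochs <- function(epochs, path) {
  m <- epochs@data
  d <- data.frame(trial = seq_len(nrow(m)))
  d <- cbind(d, as.data.frame(m))
  names(d) <- c("trial", paste0("t", seq_len(ncol(m))))
  write_tsv(d, path)
  jsonlite::write_json(list(time_s = epochs@time,
                            labels = epochs@labels),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
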