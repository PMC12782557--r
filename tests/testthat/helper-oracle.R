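# Independent brute-force re-derivation of the learner quantities from raw
# counts (tabulate per trial, explicit sums), used as the oracle against
# the sequential implementation.
oracle_learner <- function(events, alpha) {
  K <- length(alpha)
  sa <- sum(alpha)
  n <- length(events)
  out <- data.frame(trial = seq_len(n), event = events, p_pred = NA_real_,
                    I = NA_real_, H = NA_real_, DKL = NA_real_)
  for (j in seq_len(n)) {
    k <- events[j]
    cb <- tabulate(events[seq_len(j - 1)], nbins = K)
    ca <- tabulate(events[seq_len(j)], nbins = K)
    p_pred <- (cb[k] + alpha[k]) / (j - 1 + sa)
    pm_before <- (cb + alpha) / (j - 1 + sa)
    pm_after <- (ca + alpha) / (j + sa)
    out$p_pred[j] <- p_pred
    out$I[j] <- -log2(p_pred)
    out$H[j] <- -sum(pm_after * log2(pm_after))
    out$DKL[j] <- sum(pm_after * log2(pm_after / pm_before))
  }
  out
}

# all event sequences over K symbols with lengths 1..max_len
all_sequences <- function(K, max_len) {
  out <- list()
  for (len in seq_len(max_len)) {
    g <- as.matrix(expand.grid(rep(list(seq_len(K)), len)))
    out <- c(out, lapply(seq_len(nrow(g)), function(i) unname(g[i, ])))
  }
  out
}

# constant-rate recording with a known modification window
make_recording <- function(y, fs = 100) PupilRecording(y, fs = fs)

# lme4 emits a message on singular random-effect fits; harmless at the
# small simulated scales used here
suppress_singular <- function(expr)
  withCallingHandlers(expr, message = function(m) {
    if (grepl("singular", conditionMessage(m))) invokeRestart("muffleMessage")
  })
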