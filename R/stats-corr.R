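#' Trial-wise correlation time course
#'
#' For each participant and epoch timepoint, the Pearson correlation across
#' trials between a per-trial model variable and the pupil value, Fisher
#' transformed (z = atanh(r), with r clamped away from +/-1). Participants
#' whose regressor has zero variance within the chosen subset are
#' missing-coded (all-NA row) with a warning and are skipped by group
#' statistics.
#'
#' @param epochs a baseline-corrected \linkS4class{EpochSet}; its labels
#'   must contain a \code{subject} column, and an \code{accuracy} column
#'   (0/1) when subsetting.
#' @param regressor per-trial values aligned to the epoch rows, or the name
#'   of a label column.
#' @param variable name used to tag the result.
#' @param subset "all", "correct" or "error" trials.
#' @param minTrials minimum trials per participant in the subset.
#' @return A \linkS4class{CorrTimecourse}.
#' @export
correlationTimecourse <- function(epochs, regressor, variable = "x",
                                  subset = c("all", "correct", "error"),
                                  minTrials = 3) {
  subset <- match.arg(subset)
  stopifnot(is(epochs, "EpochSet"))
  lab <- epochs@labels
  if (is.character(regressor) && length(regressor) == 1L) {
    variable <- regressor
    regressor <- lab[[regressor]]
  }
  if (length(regressor) != nrow(lab))
    stop("regressor must align with epoch rows")
  if (!"subject" %in% names(lab)) stop("labels need a subject column")
  sel <- switch(subset,
                all = rep(TRUE, nrow(lab)),
                correct = lab$accuracy == 1,
                error = lab$accuracy == 0)
  subjects <- unique(lab$subject)
  z <- matrix(NA_real_, length(subjects), ncol(epochs@data))
  rownames(z) <- as.character(subjects)
  clamp <- 1 - 1e-12
  for (si in seq_along(subjects)) {
    i <- which(lab$subject == subjects[si] & sel)
    if (length(i) < minTrials) {
      warning("subject ", subjects[si], ": fewer than ", minTrials,
              " trials in subset; missing-coded")
      next
    }
    x <- regressor[i]
    if (sd(x) == 0) {
      warning("subject ", subjects[si],
              ": zero-variance regressor; missing-coded")
      next
    }
    r <- suppressWarnings(cor(x, epochs@data[i, , drop = FALSE]))
    r[is.na(r)] <- 0  # zero-variance pupil timepoint
    z[si, ] <- atanh(pmin(pmax(r, -clamp), clamp))
  }
  new("CorrTimecourse", z = z, variable = variable, time = epochs@time,
      subset = subset)
}

#' Group average of a Fisher-z time course
#'
#' Averages the Fisher-z values over participants; the displayed
#' correlation is tanh of the mean z (inference stays on z).
#'
#' @param tc a \linkS4class{CorrTimecourse}.
#' @return data.frame: time_s, mean_z, mean_r, sem (SEM of z across
#'   participants), n.
#' @export
groupAverageFisher <- function(tc) {
  stopifnot(is(tc, "CorrTimecourse"))
  z <- tc@z[rowSums(is.na(tc@z)) == 0, , drop = FALSE]
  if (nrow(z) < 2) stop("SEM undefined: need >= 2 participants")
  mz <- colMeans(z)
  data.frame(time_s = tc@time, mean_z = mz, mean_r = tanh(mz),
             sem = apply(z, 2, sd) / sqrt(nrow(z)), n = nrow(z))
}

col_t_stats <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  s <- sqrt((colSums(m^2) - n * mu^2) / (n - 1))
  t <- mu / (s / sqrt(n))
  t[!is.finite(t)] <- 0
  t
}

find_clusters <- function(t_vals, crit) {
  supra <- abs(t_vals) > crit
  sgn <- sign(t_vals)
  # runs of suprathreshold points sharing a sign
  grp <- cumsum(c(1, diff(supra * sgn) != 0))
  out <- list()
  for (g in unique(grp[supra])) {
    idx <- which(grp == g & supra)
    out[[length(out) + 1]] <- list(idx = idx, mass = sum(t_vals[idx]))
  }
  out
}

max_cluster_mass <- function(tv, crit) {
  supra <- abs(tv) > crit
  if (!any(supra)) return(0)
  r <- rle(sign(tv) * supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mx <- 0
  for (i in which(r$values != 0))
    mx <- max(mx, abs(sum(tv[starts[i]:ends[i]])))
  mx
}

#' Cluster-based sign-flip permutation test
#'
#' One-sample test of a participants x timepoints matrix against zero with
#' family-wise error control over timepoints. Per timepoint a one-sample t
#' statistic is computed; contiguous runs exceeding the two-sided critical
#' value at \code{clusterAlpha} form clusters whose mass is the sum of t
#' values. The null distribution is the maximum absolute cluster mass over
#' random sign flips of participant rows; each cluster's p value is the
#' proportion of the null at or above its absolute mass.
#'
#' @param m numeric matrix, participants x timepoints (e.g. Fisher z).
#' @param nPerm number of sign-flip permutations (>= 100).
#' @param clusterAlpha cluster-forming alpha (two-sided).
#' @param seed integer seed; recorded in the result.
#' @param time optional time axis for reporting cluster spans.
#' @return list: \code{clusters} data.frame (start_s, end_s, mass,
#'   p_value), \code{t} per-timepoint statistics, \code{nPerm},
#'   \code{clusterAlpha}, \code{seed}.
#' @export
clusterPermutationTest <- function(m, nPerm = 10000, clusterAlpha = 0.05,
                                   seed = 1, time = seq_len(ncol(m))) {
  m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  if (nrow(m) < 5) stop("need >= 5 participants")
  if (nPerm < 100) stop("unstable p: nPerm must be >= 100")
  n <- nrow(m)
  crit <- qt(1 - clusterAlpha / 2, df = n - 1)
  obs <- find_clusters(col_t_stats(m), crit)
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      mass = numeric(), p_value = numeric())
  res <- list(clusters = empty, t = col_t_stats(m), nPerm = nPerm,
              clusterAlpha = clusterAlpha, seed = seed)
  if (!length(obs)) return(res)
  # sign flips leave squared data unchanged, so all permutation t
  # statistics follow from one matrix product of the sign matrix
  S <- local({
    set.seed(seed)
    matrix(sample(c(-1, 1), n * nPerm, replace = TRUE), nPerm, n)
  })
  MU <- S %*% m / n
  VAR <- sweep(-n * MU^2, 2, colSums(m^2), "+") / (n - 1)
  Tm <- MU / sqrt(VAR / n)
  Tm[!is.finite(Tm)] <- 0
  null_max <- vapply(seq_len(nPerm), function(p)
    max_cluster_mass(Tm[p, ], crit), 0)
  res$clusters <- data.frame(
    start_s = vapply(obs, function(cl) time[cl$idx[1]], 0),
    end_s = vapply(obs, function(cl) time[cl$idx[length(cl$idx)]], 0),
    mass = vapply(obs, `[[`, 0, "mass"),
    p_value = vapply(obs, function(cl)
      mean(null_max >= abs(cl$mass)), 0))
  res
}

#' Benjamini-Hochberg rejection mask
#'
#' @param p p values in [0, 1].
#' @param q false discovery rate.
#' @return logical rejection mask.
#' @export
fdrAdjust <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  p.adjust(p, method = "BH") <= q
}
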