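#' Ideal observer over discrete event types
#'
#' A Dirichlet-categorical ideal observer watches a sequence of discrete
#' events k in 1..K and maintains a Dirichlet belief over the event
#' probability vector. After j observations with per-type counts n_k the
#' posterior is Dirichlet(alpha + n) and its mean assigns probability
#' (n_k + alpha_k) / (j + sum(alpha)) to type k. Three per-trial quantities
#' summarise each observation, all in bits:
#' \itemize{
#'   \item surprise I = -log2 of the predictive probability of the observed
#'     event, computed \emph{before} the event is absorbed;
#'   \item entropy H of the posterior-mean distribution \emph{including} the
#'     current event (the observer has seen the trial's outcome by the time
#'     feedback arrives);
#'   \item information gain D_KL, the Kullback-Leibler divergence from the
#'     pre-update to the post-update posterior mean.
#' }
#' @name ideal-learner
NULL

clip_p <- function(p) pmax(p, 1e-12)  # guard; never binds with alpha > 0

#' Construct a uniform prior
#'
#' @param K number of event types (>= 2).
#' @return A \linkS4class{PriorSpec} with alpha = rep(1, K).
#' @export
uniformPrior <- function(K) {
  if (K < 2) stop("K must be >= 2")
  new("PriorSpec", alpha = rep(1, K), source = "uniform",
      Po = numeric(), scaleMode = "pseudo_counts_sum_K")
}

#' Construct a prior from event probabilities
#'
#' @param Po probability vector over the K event types (sums to 1).
#' @param scaleMode \code{"pseudo_counts_sum_K"} multiplies Po by K so the
#'   concentrations sum to K (recovers the textbook predictive-probability
#'   denominator j - 1 + K); \code{"raw_probabilities"} uses Po directly.
#' @param source provenance tag.
#' @return A \linkS4class{PriorSpec}.
#' @export
probabilityPrior <- function(Po, scaleMode = c("pseudo_counts_sum_K",
                                               "raw_probabilities"),
                             source = "oddball_estimated") {
  scaleMode <- match.arg(scaleMode)
  if (any(Po <= 0)) stop("all Po entries must be > 0")
  if (abs(sum(Po) - 1) > 1e-9) stop("Po must sum to 1")
  alpha <- if (scaleMode == "pseudo_counts_sum_K") length(Po) * Po else Po
  new("PriorSpec", alpha = alpha, source = source, Po = Po,
      scaleMode = scaleMode)
}

#' Initialize a belief state
#'
#' @param K number of event types.
#' @param prior a \linkS4class{PriorSpec}; its alpha must have length K.
#' @return A \linkS4class{BeliefState} with zero counts.
#' @export
initBelief <- function(K, prior = uniformPrior(K)) {
  if (K < 2) stop("invalid prior: K must be >= 2")
  alpha <- priorAlpha(prior)
  if (length(alpha) != K) stop("invalid prior: alpha length must equal K")
  if (any(alpha <= 0)) stop("invalid prior: alpha must be positive")
  new("BeliefState", alpha = alpha, counts = integer(K), j = 0L)
}

#' Absorb one event
#'
#' @param state a \linkS4class{BeliefState}.
#' @param event observed event index in 1..K.
#' @return The updated \linkS4class{BeliefState}.
#' @export
updateBelief <- function(state, event) {
  K <- length(state@alpha)
  if (!is.numeric(event) || length(event) != 1L || is.na(event) ||
      event != as.integer(event) || event < 1 || event > K)
    stop("invalid event: index must be an integer in 1..K")
  counts <- state@counts
  counts[event] <- counts[event] + 1L
  new("BeliefState", alpha = state@alpha, counts = counts,
      j = state@j + 1L)
}

#' Predictive probability of an event
#'
#' Probability that the next observation is of type \code{event}, under the
#' current posterior mean: (n_k + alpha_k) / (j + sum(alpha)). With
#' concentrations summing to K this is the familiar (n_k + alpha_k)/(j + K).
#'
#' @param state a \linkS4class{BeliefState}.
#' @param event event index in 1..K; if missing, the full K-vector.
#' @return numeric probability (or vector summing to 1).
#' @export
predictiveProb <- function(state, event) {
  p <- (state@counts + state@alpha) / (state@j + sum(state@alpha))
  if (missing(event)) return(p)
  K <- length(state@alpha)
  if (event < 1 || event > K || event != as.integer(event))
    stop("invalid event: index must be an integer in 1..K")
  p[event]
}

#' Posterior-mean probability vector
#' @param state a \linkS4class{BeliefState}.
#' @return numeric K-vector summing to 1.
#' @export
posteriorMean <- function(state) {
  (state@counts + state@alpha) / (state@j + sum(state@alpha))
}

#' Shannon surprise
#'
#' @param p predictive probability of the observed event, in (0, 1].
#' @return surprise -log2(p) in bits.
#' @export
shannonSurprise <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  -log2(clip_p(p))
}

#' Shannon entropy of a distribution
#'
#' @param p probability vector (sums to 1; zeros allowed, 0*log2(0) = 0).
#' @return entropy in bits, in [0, log2(K)].
#' @export
posteriorEntropy <- function(p) {
  if (any(p < 0)) stop("invalid distribution: negative entries")
  if (abs(sum(p) - 1) > 1e-6) stop("invalid distribution: must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Kullback-Leibler divergence between two distributions
#'
#' D_KL(posterior || prior) = sum p_k log2(p_k / q_k), in bits. Used per
#' trial with the post- and pre-update posterior-mean vectors.
#'
#' @param posterior,prior probability vectors; prior entries must be
#'   positive wherever the posterior is.
#' @return divergence in bits, >= 0.
#' @export
klUpdate <- function(posterior, prior) {
  if (abs(sum(posterior) - 1) > 1e-6 || abs(sum(prior) - 1) > 1e-6)
    stop("invalid distribution: must sum to 1")
  nz <- posterior > 0
  if (any(prior[nz] <= 0))
    stop("domain error: zero prior entry with nonzero posterior entry")
  sum(posterior[nz] * log2(posterior[nz] / prior[nz]))
}

#' Run the ideal learner over an event sequence
#'
#' For each trial j: the predictive probability and surprise of the observed
#' event are computed from the belief state \emph{before} the trial; the
#' state then absorbs the trial; entropy is computed on the post-update
#' posterior mean and information gain between post- and pre-update means.
#'
#' @param events integer vector of event indices in 1..K.
#' @param prior a \linkS4class{PriorSpec} (or K for a uniform prior).
#' @param K number of event types; defaults to length(priorAlpha(prior)).
#' @return data.frame with one row per trial: trial, event, p_pred, I, H,
#'   DKL (bits).
#' @export
runLearner <- function(events, prior, K = length(priorAlpha(prior))) {
  if (is.numeric(prior) && length(prior) == 1L) {
    K <- prior
    prior <- uniformPrior(K)
  }
  alpha <- priorAlpha(prior)
  if (length(alpha) != K) stop("prior K mismatch")
  events <- as.integer(events)
  if (any(is.na(events)) || any(events < 1L) || any(events > K))
    stop("invalid event: indices must lie in 1..K")
  n <- length(events)
  sa <- sum(alpha)
  counts <- numeric(K)
  p_pred <- I <- H <- DKL <- numeric(n)
  pm_prev <- alpha / sa
  for (t in seq_len(n)) {
    k <- events[t]
    p <- (counts[k] + alpha[k]) / (t - 1 + sa)
    counts[k] <- counts[k] + 1
    pm <- (counts + alpha) / (t + sa)
    p_pred[t] <- p
    I[t] <- -log2(clip_p(p))
    nzpm <- clip_p(pm)
    H[t] <- -sum(pm * log2(nzpm))
    DKL[t] <- sum(pm * log2(nzpm / clip_p(pm_prev)))
    pm_prev <- pm
  }
  data.frame(trial = seq_len(n), event = events, p_pred = p_pred,
             I = I, H = H, DKL = DKL)
}

#' Estimate a prior from an odd-ball exposure sequence
#'
#' Final event-type probabilities at the end of an odd-ball exposure phase,
#' add-one smoothed over regular (non-odd-ball) trials only:
#' P_o,k = (n_k + 1) / (N_reg + K), renormalized to sum to 1. Odd-ball
#' trials carry no letter-color event and are skipped entirely.
#'
#' @param events integer event indices in 1..K for regular trials; entries
#'   for odd-ball trials are ignored (may be NA).
#' @param isOddball logical per-trial flag.
#' @param K number of event types (default 36 for a 6 x 6 pair space).
#' @param scaleMode passed to \code{\link{probabilityPrior}}.
#' @return A \linkS4class{PriorSpec} with source "oddball_estimated".
#' @export
oddballPrior <- function(events, isOddball, K = 36,
                         scaleMode = "pseudo_counts_sum_K") {
  reg <- events[!isOddball]
  if (!length(reg)) stop("degenerate prior: no regular trials")
  if (any(is.na(reg)) || any(reg < 1) || any(reg > K))
    stop("invalid event: regular-trial indices must lie in 1..K")
  n_k <- tabulate(reg, nbins = K)
  Po <- (n_k + 1) / (length(reg) + K)
  Po <- Po / sum(Po)
  probabilityPrior(Po, scaleMode = scaleMode)
}
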