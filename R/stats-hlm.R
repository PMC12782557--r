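#' Random-intercept models of the window-mean pupil response
#'
#' Model 1 regresses the window-mean feedback-locked pupil response on the
#' three ideal-learner variables plus nuisance covariates with a random
#' intercept per subject:
#' \code{pupil ~ I + H + DKL + baseline + rt + (1 | subject)}.
#' Model 2 adds the H x DKL interaction. Models are fit by maximum
#' likelihood (lme4) and compared on a K-fold cross-validated expected log
#' predictive density (ELPD): pointwise Gaussian log predictive densities
#' of held-out trials under the training fit. A difference in ELPD is
#' called meaningful when |dELPD| exceeds twice its standard error,
#' estimated from the pointwise differences.
#' @name hlm
NULL

hlm_formula <- function(modelId) {
  if (modelId == 1)
    pupil ~ I + H + DKL + baseline + rt + (1 | subject)
  else
    pupil ~ I + H + DKL + H:DKL + baseline + rt + (1 | subject)
}

#' Fit a random-intercept model with cross-validated ELPD
#'
#' @param trialTable data.frame with columns pupil, I, H, DKL, baseline,
#'   rt, subject.
#' @param modelId 1 (main effects) or 2 (adds H:DKL).
#' @param nFolds cross-validation folds (trials stratified by subject so
#'   every training set contains every subject).
#' @param seed fold-assignment seed.
#' @param zScore z-score the predictors before fitting.
#' @return list: \code{modelId}, \code{fit} (merMod), \code{coefficients}
#'   data.frame (term, estimate, lower, upper, pd), \code{elpd},
#'   \code{elpdPointwise}, \code{nFolds}.
#' @export
fitHlm <- function(trialTable, modelId = 1, nFolds = 10, seed = 1,
                   zScore = FALSE) {
  need <- c("pupil", "I", "H", "DKL", "baseline", "rt", "subject")
  stopifnot(all(need %in% names(trialTable)))
  if (length(unique(trialTable$subject)) < 2)
    stop("invalid grouping: need >= 2 subjects")
  dat <- trialTable
  dat$subject <- factor(dat$subject)
  if (zScore)
    for (v in c("I", "H", "DKL", "baseline", "rt"))
      dat[[v]] <- as.vector(scale(dat[[v]]))
  form <- hlm_formula(modelId)
  X <- model.matrix(lme4::nobars(form), dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinearity error: rank-deficient design, offending columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- lme4::lmer(form, data = dat, REML = FALSE)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      lower = unname(est - 1.96 * se),
                      upper = unname(est + 1.96 * se),
                      pd = 100 * pnorm(abs(unname(est)) / se))
  # K-fold CV, folds stratified within subject
  n <- nrow(dat)
  folds <- integer(n)
  set.seed(seed)
  for (s in levels(dat$subject)) {
    i <- which(dat$subject == s)
    folds[i] <- sample(rep_len(seq_len(nFolds), length(i)))
  }
  lpd <- numeric(n)
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    fit_f <- lme4::lmer(form, data = dat[tr, , drop = FALSE], REML = FALSE)
    mu <- predict(fit_f, newdata = dat[!tr, , drop = FALSE],
                  allow.new.levels = TRUE)
    lpd[!tr] <- dnorm(dat$pupil[!tr], mu, sigma(fit_f), log = TRUE)
  }
  list(modelId = modelId, fit = fit, coefficients = coefs,
       elpd = sum(lpd), elpdPointwise = lpd, nFolds = nFolds)
}

#' Fit and compare Model 1 and Model 2
#'
#' @param trialTable as in \code{\link{fitHlm}}.
#' @param nFolds,seed,zScore passed to \code{\link{fitHlm}}.
#' @return list: \code{model1}, \code{model2} (each a \code{fitHlm}
#'   result), \code{dElpd} (model2 - model1), \code{se}, \code{ratio},
#'   \code{meaningful} (TRUE iff |ratio| > 2), \code{preferred} (1 or 2).
#' @export
fitAndCompareHlm <- function(trialTable, nFolds = 10, seed = 1,
                             zScore = FALSE) {
  m1 <- fitHlm(trialTable, 1, nFolds = nFolds, seed = seed, zScore = zScore)
  m2 <- fitHlm(trialTable, 2, nFolds = nFolds, seed = seed, zScore = zScore)
  dpw <- m2$elpdPointwise - m1$elpdPointwise
  d <- sum(dpw)
  se <- sd(dpw) * sqrt(length(dpw))
  ratio <- if (se > 0) abs(d) / se else Inf
  list(model1 = m1, model2 = m2, dElpd = d, se = se, ratio = ratio,
       meaningful = ratio > 2,
       preferred = if (d > 0 && ratio > 2) 2L else 1L)
}
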