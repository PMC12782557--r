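test_that("prior construction resolves scale modes and rejects bad input", {
  expect_equal(priorAlpha(uniformPrior(4)), rep(1, 4))
  # K * (1/K) = 1: a uniform probability prior gives unit pseudo-counts
  expect_equal(priorAlpha(probabilityPrior(rep(1 / 36, 36))), rep(1, 36))
  expect_equal(priorAlpha(probabilityPrior(c(0.5, 0.25, 0.125, 0.125))),
               c(2, 1, 0.5, 0.5))
  expect_equal(priorAlpha(probabilityPrior(c(0.5, 0.25, 0.125, 0.125),
                                           "raw_probabilities")),
               c(0.5, 0.25, 0.125, 0.125))
  expect_error(probabilityPrior(c(0.5, 0.6)), "sum to 1")
  expect_error(probabilityPrior(c(0.5, 0.5, 0)), "> 0")
  expect_error(initBelief(1), "K must be >= 2")
  expect_error(initBelief(3, uniformPrior(4)), "length")
})

test_that("belief updating increments counts and validates events", {
  st <- initBelief(4)
  expect_equal(eventCounts(st), integer(4))
  expect_equal(nObserved(st), 0L)
  # concentrated prior worked example: observing type 2 under [100,1,1,1]
  pr <- new("PriorSpec", alpha = c(100, 1, 1, 1), source = "uniform",
            Po = numeric(), scaleMode = "raw_probabilities")
  b <- updateBelief(initBelief(4, pr), 2)
  expect_equal(priorAlpha(b) + eventCounts(b), c(100, 2, 1, 1))
  # counting
  st3 <- Reduce(updateBelief, rep(1, 3), initBelief(4))
  expect_equal(eventCounts(st3), c(3L, 0L, 0L, 0L))
  expect_equal(nObserved(st3), 3L)
  expect_error(updateBelief(st, 5), "invalid event")
  expect_error(updateBelief(st, 0), "invalid event")
})

test_that("predictive probabilities follow the posterior mean and normalize", {
  st <- initBelief(4)
  expect_equal(predictiveProb(st, 1), 0.25)
  st1 <- updateBelief(st, 1)
  expect_equal(predictiveProb(st1, 1), 2 / 5)
  # normalization across many random states
  set.seed(7)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    st <- initBelief(K, probabilityPrior(prop.table(runif(K))))
    for (e in sample(K, 15, replace = TRUE)) st <- updateBelief(st, e)
    expect_equal(sum(predictiveProb(st)), 1, tolerance = 1e-9)
    expect_equal(sum(posteriorMean(st)), 1, tolerance = 1e-9)
  }
})

test_that("surprise, entropy and KL divergence match closed forms", {
  expect_equal(shannonSurprise(0.5), 1)
  expect_equal(shannonSurprise(1), 0)
  expect_equal(shannonSurprise(0.25), 2)
  expect_error(shannonSurprise(0), "in \\(0, 1\\]")
  expect_equal(posteriorEntropy(rep(0.25, 4)), 2)
  expect_equal(posteriorEntropy(c(1, 0, 0, 0)), 0)
  expect_equal(posteriorEntropy(c(0.4, 0.4, 0.1, 0.1)), 1.7219281,
               tolerance = 1e-6)
  expect_error(posteriorEntropy(c(0.5, 0.4)), "sum to 1")
  expect_equal(klUpdate(rep(0.25, 4), rep(0.25, 4)), 0)
  expect_equal(klUpdate(c(0.4, 0.2, 0.2, 0.2), rep(0.25, 4)), 0.0780719,
               tolerance = 1e-6)
  set.seed(3)
  for (i in 1:25) {
    p <- prop.table(runif(4)); q <- prop.table(runif(4))
    expect_gte(klUpdate(p, q), 0)
  }
})

test_that("runLearner chains the per-trial quantities correctly", {
  r1 <- runLearner(1, uniformPrior(4))
  expect_equal(r1$p_pred, 0.25)
  expect_equal(r1$I, 2)
  expect_equal(r1$H, 1.9219281, tolerance = 1e-6)
  expect_equal(r1$DKL, 0.0780719, tolerance = 1e-6)
  r2 <- runLearner(c(1, 1), uniformPrior(4))
  expect_equal(r2$p_pred[2], 0.4)
  expect_equal(r2$I[2], 1.3219281, tolerance = 1e-6)
})

test_that("sequential learner agrees with the brute-force count oracle", {
  set.seed(11)
  for (i in 1:10) {
    K <- sample(2:4, 1)
    ev <- sample(K, 20, replace = TRUE)
    prior <- if (i %% 2) uniformPrior(K) else
      probabilityPrior(prop.table(runif(K) + 0.2))
    got <- runLearner(ev, prior)
    want <- oracle_learner(ev, priorAlpha(prior))
    expect_equal(got$p_pred, want$p_pred, tolerance = 1e-9)
    expect_equal(got$I, want$I, tolerance = 1e-9)
    expect_equal(got$H, want$H, tolerance = 1e-9)
    expect_equal(got$DKL, want$DKL, tolerance = 1e-9)
  }
})

test_that("information gain decays over stationary sequences", {
  set.seed(5)
  for (i in 1:10) {
    ev <- sample(4, 200, replace = TRUE, prob = c(0.4, 0.1, 0.4, 0.1))
    r <- runLearner(ev, uniformPrior(4))
    expect_lt(mean(r$DKL[151:200]), mean(r$DKL[1:50]))
    expect_true(all(r$DKL >= 0))
    expect_true(all(r$H >= 0 & r$H <= 2 + 1e-12))
  }
})

test_that("odd-ball prior applies add-one smoothing over regular trials", {
  # toy: counts [4,3,2,1] over 10 regular trials, K = 4
  ev <- rep(1:4, c(4, 3, 2, 1))
  pr <- oddballPrior(ev, rep(FALSE, 10), K = 4)
  expect_equal(pr@Po, c(5, 4, 3, 2) / 14, tolerance = 1e-12)
  expect_equal(pr@source, "oddball_estimated")
  # symmetric exposure: uniform final probabilities
  pr0 <- oddballPrior(rep(1:36, 2), rep(FALSE, 72), K = 36)
  expect_equal(pr0@Po, rep(1 / 36, 36))
  expect_error(oddballPrior(integer(), logical(), K = 4), "degenerate")
  # odd-ball trials are skipped, not counted
  ev2 <- c(ev, 1, 1)
  pr2 <- oddballPrior(ev2, c(rep(FALSE, 10), TRUE, TRUE), K = 4)
  expect_equal(pr2@Po, pr@Po)
})

test_that("entropy trajectories rise with concentrated priors on balanced data
           and fall with uniform priors on skewed data", {
  ct <- runLearner(genCueTargetSequence(seed = 1)$event, uniformPrior(4))
  expect_lt(mean(ct$H[151:200]), mean(ct$H[1:50]))
  ob <- genOddballSequence(seed = 1)
  pr <- oddballPrior(ob$trials$event, ob$trials$is_oddball)
  lc <- runLearner(genLettercolorSequence(ob$assignment, seed = 2)$event, pr)
  expect_gt(mean(lc$H[201:250]), mean(lc$H[1:50]))
})
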