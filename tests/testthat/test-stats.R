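make_epochs <- function(nSubj, nTrial, nTime, fill = 0) {
  n <- nSubj * nTrial
  new("EpochSet", data = matrix(fill, n, nTime),
      time = seq(0, by = 0.02, length.out = nTime),
      baselines = numeric(),
      labels = data.frame(subject = rep(seq_len(nSubj), each = nTrial),
                          trial = rep(seq_len(nTrial), nSubj),
                          accuracy = rep_len(c(0, 1), n)))
}

test_that("correlation time course computes per-subject Fisher z", {
  set.seed(1)
  ep <- make_epochs(4, 50, 20)
  ep@data <- matrix(rnorm(length(ep@data)), nrow(ep@data))
  # regressor equal to the pupil at timepoint 7: clamped r = 1 there
  x <- ep@data[, 7]
  tc <- correlationTimecourse(ep, x, variable = "self")
  z <- fisherZ(tc)
  expect_true(all(z[, 7] > 13))  # atanh(1 - 1e-12) ~ 14.2
  expect_true(all(abs(z[, -7]) < 1))
  # independent regressor: near-zero mean r across seeds
  mean_r <- replicate(20, {
    tc0 <- correlationTimecourse(ep, rnorm(nrow(ep@data)))
    mean(tanh(fisherZ(tc0)))
  })
  expect_lt(abs(mean(mean_r)), 0.05)
  # zero-variance regressor missing-codes that subject
  xx <- rnorm(nrow(ep@data))
  xx[ep@labels$subject == 2] <- 1
  expect_warning(tc2 <- correlationTimecourse(ep, xx), "zero-variance")
  expect_true(all(is.na(fisherZ(tc2)[2, ])))
  expect_true(all(!is.na(fisherZ(tc2)[-2, ])))
})

test_that("group Fisher averaging works on z and back-transforms for display", {
  tc <- new("CorrTimecourse", z = rbind(c(0.2, 0), c(0.4, 0)),
            variable = "x", time = c(0, 1), subset = "all")
  g <- groupAverageFisher(tc)
  expect_equal(g$mean_z[1], 0.3)
  expect_equal(g$mean_r[1], tanh(0.3))
  expect_equal(g$mean_z[2], 0)
  tc1 <- new("CorrTimecourse", z = matrix(0.5, 1, 2), variable = "x",
             time = c(0, 1), subset = "all")
  expect_error(groupAverageFisher(tc1), ">= 2 participants")
})

test_that("cluster permutation test finds planted effects and scales invariantly", {
  expect_equal(nrow(clusterPermutationTest(matrix(0, 8, 30),
                                           nPerm = 200)$clusters), 0)
  set.seed(3)
  m <- matrix(rnorm(24 * 100), 24)
  m[, 40:60] <- m[, 40:60] + 1
  r <- clusterPermutationTest(m, nPerm = 500, seed = 4)
  sig <- r$clusters[r$clusters$p_value < 0.05, ]
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$start_s <= 60 & sig$end_s >= 40))
  # p values invariant to common scaling
  r2 <- clusterPermutationTest(5 * m, nPerm = 500, seed = 4)
  expect_equal(r$clusters$p_value, r2$clusters$p_value)
  expect_error(clusterPermutationTest(m, nPerm = 50), "unstable")
  expect_error(clusterPermutationTest(m[1:3, ], nPerm = 200), ">= 5")
})

test_that("BH step-up rejects the right hypotheses and is monotone in q", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.04, 0.2), q = 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(fdrAdjust(rep(0.001, 10))))
  expect_false(any(fdrAdjust(rep(1, 10))))
  set.seed(5)
  p <- runif(50)^2
  r1 <- fdrAdjust(p, q = 0.02)
  r2 <- fdrAdjust(p, q = 0.1)
  expect_true(all(r2[r1]))
})

test_that("repeated-measures ANOVA matches aov strata and pingouin exactly", {
  set.seed(42)
  d <- expand.grid(subject = 1:10, A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  d$value <- rnorm(nrow(d)) + ifelse(d$A == "a2", 0.5, 0) +
    as.numeric(factor(d$B)) * 0.3 + rep(rnorm(10), 6)
  r <- windowFactorialAnova(d, c("A", "B"))$effects
  # dual route: aov with within-subject error strata
  da <- transform(d, subject = factor(subject))
  fit <- summary(aov(value ~ A * B + Error(subject / (A * B)), data = da))
  aovF <- c(fit[["Error: subject:A"]][[1]]["A", "F value"],
            fit[["Error: subject:B"]][[1]]["B", "F value"],
            fit[["Error: subject:A:B"]][[1]]["A:B", "F value"])
  expect_equal(r$F, aovF, tolerance = 1e-6)
  # frozen reference values from an independent implementation
  expect_equal(r$F, c(0.284111, 1.425093, 0.737055), tolerance = 1e-4)
  expect_equal(r$p_GG, c(0.606928, 0.267230, 0.488134), tolerance = 1e-4)
  expect_equal(r$eps_GG, c(1, 0.917348, 0.963304), tolerance = 1e-4)
  expect_equal(r$ges, c(0.008233, 0.040005, 0.017558), tolerance = 1e-4)
})

test_that("ANOVA edge cases: flat data, pure interaction, missing cells", {
  d <- expand.grid(subject = 1:6, A = c("a1", "a2"), B = c("b1", "b2"))
  d$value <- 1
  r <- windowFactorialAnova(d, c("A", "B"))$effects
  expect_equal(r$F, rep(0, 3))
  # pure interaction: +1 on (a1,b1) and (a2,b2), -1 elsewhere, plus tiny
  # subject noise so error terms are nonzero
  set.seed(8)
  d$value <- ifelse((d$A == "a1") == (d$B == "b1"), 1, -1) +
    rnorm(nrow(d), 0, 0.01)
  r2 <- windowFactorialAnova(d, c("A", "B"))$effects
  expect_gt(r2$F[r2$effect == "A:B"], 1000)
  expect_lt(r2$F[r2$effect == "A"], 10)
  expect_lt(r2$F[r2$effect == "B"], 10)
  # subject with a missing cell is excluded and reported
  d3 <- d[!(d$subject == 6 & d$A == "a2" & d$B == "b2"), ]
  expect_warning(r3 <- windowFactorialAnova(d3, c("A", "B")), "excluded")
  expect_equal(r3$excluded, "6")
  expect_equal(r3$nSubjects, 5)
})

test_that("Wilcoxon signed-rank handles exact and approximate regimes", {
  r <- pairedNonparametricTest(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_equal(r$p, 2 / 64)
  expect_equal(r$r_rb, 1)
  expect_equal(r$method, "exact")
  expect_error(pairedNonparametricTest(1:6, 1:6), "undefined test")
  # antisymmetric differences: balanced ranks, zero effect size
  x <- c(1, 2, 3, -1, -2, -3)
  r2 <- pairedNonparametricTest(x, rep(0, 6))
  expect_equal(r2$r_rb, 0)
  # cross-check against the reference implementation, exact regime
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(12)
    ours <- pairedNonparametricTest(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # large-sample normal approximation against the reference
  set.seed(10)
  a <- rnorm(60); b <- rnorm(60, 0.3)
  ours <- pairedNonparametricTest(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
  expect_equal(ours$method, "normal approximation")
})
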