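test_that("derivative artifact detection flags steps and ignores smooth signals", {
  expect_equal(nrow(artifactIntervals(
    detectDerivativeArtifacts(make_recording(rep(5, 1000))))), 0)
  # one step of height 50 at t = 5 s
  y <- rep(0, 1000); y[501:1000] <- 50
  iv <- artifactIntervals(detectDerivativeArtifacts(make_recording(y)))
  expect_equal(nrow(iv), 1)
  expect_true(iv$start_s <= 5 && iv$end_s >= 5)
  # smooth 0.5 Hz unit sinusoid at 500 Hz: max step ~ pi/500 << 10
  tt <- seq(0, 10, by = 1 / 500)
  rec <- PupilRecording(sin(2 * pi * 0.5 * tt), fs = 500)
  expect_equal(nrow(artifactIntervals(detectDerivativeArtifacts(rec))), 0)
})

test_that("interpolation is exact on lines and leaves clean samples alone", {
  ann <- ArtifactAnnotations("missing", 4, 4.2)
  # flat trace: interpolation is the identity
  flat <- interpolateIntervals(make_recording(rep(3, 1000)), ann)
  expect_equal(pupilSize(flat), rep(3, 1000))
  # linear ramp exactly recovered through a 0.2 s gap
  ramp <- seq(0, 10, length.out = 1001)[-1]
  rec <- make_recording(ramp)
  out <- interpolateIntervals(rec, ann)
  expect_equal(pupilSize(out), ramp, tolerance = 1e-9)
  # samples outside the padded interval untouched for a noisy trace
  set.seed(1)
  noisy <- rnorm(1000)
  outn <- interpolateIntervals(make_recording(noisy), ann)
  t <- sampleTimes(rec)
  outside <- t < 4 - 0.15 - 1e-9 | t > 4.2 + 0.15 + 1e-9
  expect_equal(pupilSize(outn)[outside], noisy[outside])
  expect_false(isTRUE(all.equal(pupilSize(outn)[!outside], noisy[!outside])))
  # two gaps 0.1 s apart merge into one interpolation span: the clean
  # samples between them are replaced too
  ann2 <- ArtifactAnnotations(c("missing", "missing"), c(4, 4.5), c(4.2, 4.7))
  out2 <- interpolateIntervals(make_recording(noisy), ann2)
  between <- t > 4.2 & t < 4.5
  expect_false(any(pupilSize(out2)[between] == noisy[between]))
})

test_that("band-pass rejects DC, passes the band, attenuates above it", {
  fs <- 500
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  const <- bandpassFilter(PupilRecording(rep(7, length(tt)), fs = fs))
  expect_lt(max(abs(pupilSize(const))), 1e-6 * 7)
  central <- tt > 10 & tt < 50
  in_band <- bandpassFilter(PupilRecording(sin(2 * pi * 1 * tt), fs = fs))
  gain <- max(abs(pupilSize(in_band)[central]))
  expect_gt(gain, 0.9); expect_lt(gain, 1.1)
  stop_band <- bandpassFilter(PupilRecording(sin(2 * pi * 20 * tt), fs = fs))
  expect_lt(max(abs(pupilSize(stop_band)[central])), 0.1)
  expect_error(bandpassFilter(PupilRecording(rnorm(100), fs = 10)),
               "Nyquist")
})

test_that("deconvolution recovers planted kernels and is a no-op without events", {
  fs <- 50
  n <- 60 * fs
  rec <- PupilRecording(rnorm(n), fs = fs)
  out <- removeNuisanceResponses(rec, ArtifactAnnotations())
  expect_equal(pupilSize(out$recording), pupilSize(rec))
  # planted blink kernel, 20 events, noiseless
  kern <- pupilIrf(seq(0, 4, by = 1 / fs), w = 6, tmax = 1.2)
  onsets <- seq(2, 55, length.out = 20)
  y <- rep(0, n)
  for (on in onsets) {
    i0 <- round(on * fs) + 1
    idx <- i0:(i0 + length(kern) - 1)
    y[idx] <- y[idx] + kern
  }
  rec <- PupilRecording(y, fs = fs)
  ann <- ArtifactAnnotations(rep("blink", 20), onsets - 0.1, onsets)
  res <- removeNuisanceResponses(rec, ann)
  expect_lt(sqrt(mean(pupilSize(res$recording)^2)) / sqrt(mean(y^2)), 0.01)
  est <- res$irf$blink$coef
  truth <- pupilIrf(res$irf$blink$lag_s, w = 6, tmax = 1.2)
  expect_gt(cor(est, truth), 0.99)
  # two distinct kernels under moderate noise (SNR 5)
  kern2 <- pupilIrf(seq(0, 4, by = 1 / fs), w = 12, tmax = 0.6)
  on2 <- seq(3.3, 54, length.out = 15)
  y2 <- y
  for (on in on2) {
    i0 <- round(on * fs) + 1
    idx <- i0:(i0 + length(kern2) - 1)
    y2[idx] <- y2[idx] - 0.8 * kern2
  }
  set.seed(2)
  y2 <- y2 + rnorm(n, 0, sd(y2) / 5)
  ann2 <- ArtifactAnnotations(c(rep("blink", 20), rep("saccade", 15)),
                              c(onsets - 0.1, on2 - 0.05),
                              c(onsets, on2))
  res2 <- removeNuisanceResponses(PupilRecording(y2, fs = fs), ann2)
  expect_gt(cor(res2$irf$blink$coef,
                pupilIrf(res2$irf$blink$lag_s, w = 6, tmax = 1.2)),
            0.95)
  expect_gt(cor(res2$irf$saccade$coef,
                -pupilIrf(res2$irf$saccade$lag_s, w = 12,
                          tmax = 0.6)), 0.95)
})

test_that("percent signal change is a positive-reference rescaling", {
  rec <- make_recording(rep(0, 100))
  expect_equal(pupilSize(percentSignalChange(rec, 5)), rep(0, 100))
  rec2 <- make_recording(rep(0.5, 100))
  expect_equal(pupilSize(percentSignalChange(rec2, 5)), rep(10, 100))
  set.seed(4)
  y <- rnorm(100)
  expect_equal(pupilSize(percentSignalChange(make_recording(3 * y), 5)),
               3 * pupilSize(percentSignalChange(make_recording(y), 5)))
  expect_error(percentSignalChange(rec, 0), "invalid reference")
})

test_that("the full chain reduces to band-pass + scaling on clean traces", {
  fs <- 100
  tt <- seq(0, 40 - 1 / fs, by = 1 / fs)
  y <- 1000 + 5 * sin(2 * pi * 0.5 * tt)
  rec <- PupilRecording(y, fs = fs)
  pre <- preprocessPupil(rec, derivThreshold = 50)
  direct <- percentSignalChange(bandpassFilter(rec), mean(y))
  expect_equal(pupilSize(pre$recording), pupilSize(direct), tolerance = 1e-9)
  expect_equal(pre$referenceMean, mean(y))
})

test_that("RT outlier exclusion applies the 3-SD z rule per participant", {
  expect_warning(r <- excludeRtOutliers(rep(0.5, 10)), "zero RT variance")
  expect_true(all(r$keep))
  set.seed(6)
  rt <- c(rnorm(99, 0.5, 0.01), 5)
  r <- excludeRtOutliers(rt)
  expect_equal(which(!r$keep), 100L)
  # standard normal: excluded fraction ~ 2 * pnorm(-3) = 0.27 %
  set.seed(7)
  r2 <- excludeRtOutliers(rnorm(10000))
  expect_lt(abs(r2$excludedFraction - 0.0027), 0.0015)
})
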