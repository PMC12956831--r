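# Confound controls: aperiodic slope, evoked amplitude, waveform asymmetry.

test_that("aperiodic fit recovers exact power laws and ignores scale", {
  f <- seq(1, 150, by = 0.5)
  fit2 <- fitAperiodic(1e3 * f^-2, freqs = f)
  expect_equal(fit2$exponent, 2, tolerance = 0.01)
  expect_true(fit2$converged)
  # flat (white) spectrum
  expect_equal(fitAperiodic(rep(2.5, length(f)), freqs = f)$exponent, 0,
               tolerance = 0.01)
  # multiplying the PSD by a constant moves only the offset
  fitA <- fitAperiodic(f^-1, freqs = f)
  fitB <- fitAperiodic(50 * f^-1, freqs = f)
  expect_equal(fitA$exponent, fitB$exponent, tolerance = 1e-10)
  expect_equal(fitB$offset - fitA$offset, log(50), tolerance = 1e-8)
  expect_error(fitAperiodic(f[1:5]^-1, freqs = f[1:5]), ">= 10")
})

test_that("an oscillatory bump is excluded from the aperiodic fit", {
  f <- seq(1, 150, by = 0.5)
  bg <- 2 * f^-1
  psd <- bg + 3 * dnorm(f, 10, 1)
  fit <- fitAperiodic(psd, freqs = f)
  ref <- fitAperiodic(bg, freqs = f)
  expect_equal(fit$exponent, ref$exponent, tolerance = 0.05)
  expect_equal(fit$exponent, 1, tolerance = 0.05)
  expect_true(any(!fit$included[f[f >= 1] > 8 & f[f >= 1] < 12]))
})

test_that("aperiodic exponent versus distance recovers constructed slopes", {
  # noiseless construction: two distances, exponents 1.0 and 1.5
  f <- seq(1, 150, by = 1)
  es <- list()
  fs <- 600
  set.seed(20)
  mk <- function(chi, m) {
    p <- signalParams(thetaAmpBase = 1e-9, thetaHighAmpBase = 0,
                      gammaAmp = c(slow = 0, fast = 0), noiseExponent = chi)
    vapply(seq_len(m), function(i)
      as.numeric(generateEpoch(p, 0, 3.5, seed = 400 + chi * 100 + i,
                               tStart = -1.75)),
      numeric(2100))
  }
  sig <- cbind(mk(1, 12), mk(1.5, 12))
  lab <- data.frame(steps_remaining = rep(c(2L, 3L), each = 12),
                    trial_number = 1:24)
  es <- EpochSet(sig, sampleRate = fs, labels = lab, tStart = -1.75)
  out <- aperiodicVsDistance(es, window = c(-1, 1))
  expect_equal(out$slope, 0.5, tolerance = 0.15)
  expect_error(aperiodicVsDistance(es[, 1:12], window = c(-1, 1)),
               "2 distance levels")
})

test_that("asymmetry index is zero for sinusoids, exact on constructed cycles, antisymmetric in time", {
  fs <- 600; tm <- (0:(8 * fs - 1)) / fs
  pure <- asymmetryIndex(matrix(sin(2 * pi * 4 * tm)), band = c(2, 5),
                         sampleRate = fs)
  expect_lt(abs(pure$ai), 0.01)   # extrema timing is sample-quantized
  expect_gte(pure$n_cycles, 3)
  skew <- injectAsymmetry(cos(2 * pi * 3 * tm - pi), 0.25, 3, fs)
  aiF <- asymmetryIndex(matrix(skew), band = NULL, sampleRate = fs)
  expect_equal(aiF$ai, 0.25, tolerance = 0.01)
  # time reversal flips the sign exactly
  aiR <- asymmetryIndex(matrix(rev(skew)), band = NULL, sampleRate = fs)
  expect_equal(aiR$ai, -aiF$ai, tolerance = 0.01)
  # amplitude scaling and offsets leave the index unchanged
  aiS <- asymmetryIndex(matrix(5 * skew + 2), band = NULL, sampleRate = fs)
  expect_equal(aiS$ai - 0, aiF$ai, tolerance = 0.05)
  expect_true(is.na(asymmetryIndex(matrix(sin(2 * pi * 4 * tm[1:400])),
                                   band = NULL, sampleRate = fs)$ai))
})

test_that("per-cycle arithmetic matches the duration definition", {
  # one cycle with 150 ms ascent and 100 ms descent -> AI = 0.2
  fs <- 1000
  asc <- 0.15; desc <- 0.1
  cyc <- c(seq(-1, 1, length.out = asc * fs), seq(1, -1, length.out = desc * fs))
  x <- rep(cyc, 8)
  ai <- asymmetryIndex(matrix(x), band = NULL, sampleRate = fs)
  expect_equal(ai$ai, (asc - desc) / (asc + desc), tolerance = 0.02)
})

test_that("constant asymmetry yields a null asymmetry-distance slope", {
  ses <- simulateAgent(generateSession(nTrials = 40, seed = 23), seed = 24)
  p <- signalParams(asymmetry = 0.2, gammaAmp = c(slow = 0, fast = 0))
  es <- generateParticipant(p, ses, events = "move",
                            moveWindow = c(-1.75, 1.75), seed = 25)
  out <- asymmetryVsDistance(es, window = c(-1, 1))
  ai <- asymmetryIndex(es, window = c(-1, 1))
  expect_lt(abs(out$slope), 3 * sd(ai$ai, na.rm = TRUE) /
              sqrt(sum(!is.na(ai$ai))))
  # zero asymmetry everywhere: index near zero and slope near zero
  p0 <- signalParams(gammaAmp = c(slow = 0, fast = 0))
  es0 <- generateParticipant(p0, ses, events = "move",
                             moveWindow = c(-1.75, 1.75), seed = 26)
  ai0 <- asymmetryIndex(es0, window = c(-1, 1))
  expect_lt(abs(mean(ai0$ai, na.rm = TRUE)), 0.05)
})

test_that("evoked profiles behave on degenerate subsampling cases", {
  # identical epochs per distance: profile equals the single-epoch amplitude
  fs <- 600
  tm <- seq(-1.5, 1.5 - 1 / fs, by = 1 / fs)
  mk <- function(a) a * exp(-(tm - 0.2)^2 / (2 * 0.05^2)) * cos(2 * pi * 4 * (tm - 0.2))
  sig <- cbind(mk(1), mk(1), mk(2), mk(2))
  es <- EpochSet(sig, sampleRate = fs,
                 labels = data.frame(steps_remaining = c(3L, 3L, 4L, 4L)),
                 time = tm)
  ev <- evokedAmplitudeByDistance(es, window = c(-0.5, 1), nIter = 3, seed = 1)
  expect_identical(ev$profile$distance, c(3L, 4L))
  # amplitude scales linearly with the transient amplitude
  expect_equal(ev$profile$amplitude[2] / ev$profile$amplitude[1], 2,
               tolerance = 0.01)
  # subsample size = full size: iterations are identical, seed irrelevant
  ev2 <- evokedAmplitudeByDistance(es, window = c(-0.5, 1), nIter = 2, seed = 99)
  expect_equal(ev2$profile$amplitude, ev$profile$amplitude, tolerance = 1e-9)
})

test_that("random-phase induced oscillations cancel out of the evoked average", {
  ses <- fixedSession(60)
  p <- signalParams(noiseScale = 0.2, gammaAmp = c(slow = 0, fast = 0))
  mv <- generateParticipant(p, ses, events = "move", moveWindow = c(-1.75, 1.75),
                            seed = 27)
  evInduced <- evokedAmplitudeByDistance(mv, window = c(-1, 1), nIter = 10,
                                         maxDistance = 4, seed = 28)
  # reference scale: the same band amplitude of one single epoch
  tfr1 <- morletTFR(signalMatrix(mv)[, 1, drop = FALSE],
                    freqs = seq(2, 5, length.out = 4), sampleRate = 600,
                    times = epochTimes(mv))
  idx <- which(epochTimes(mv) >= -1 & epochTimes(mv) <= 1)
  ok <- tfr1@valid[, idx]
  scale1 <- mean(sqrt(exp(tfr1@values[, idx, 1][ok])))
  # the random-phase induced rhythm cancels to ~ 1/sqrt(n) of one epoch
  expect_lt(max(evInduced$profile$amplitude), 0.35 * scale1)
  # adding a genuine evoked transient restores a large average
  evAdd <- evokedAmplitudeByDistance(injectEvoked(mv, 2, 0.2, 0.4),
                                     window = c(-1, 1), nIter = 10, seed = 29)
  expect_gt(min(evAdd$profile$amplitude), 2 * max(evInduced$profile$amplitude))
})
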