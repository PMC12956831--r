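# Generative model: theta carrier, load-dependent gamma bursts, 1/f
# background, waveform skew and evoked transients.

test_that("zero items with no noise degenerates to a pure theta sinusoid", {
  p <- signalParams(noiseScale = 0, thetaHighAmpBase = 0,
                    gammaAmp = c(slow = 0, fast = 0))
  e <- generateEpoch(p, 0, 2, seed = 3)
  tm <- attr(e, "time")
  fit <- lm(e ~ cos(2 * pi * 4 * tm) + sin(2 * pi * 4 * tm))
  expect_lt(sd(resid(fit)), 1e-10)
  expect_equal(sqrt(sum(coef(fit)[2:3]^2)), 1, tolerance = 1e-6)
})

test_that("epoch generation is bit-identical under a seed and independent across seeds", {
  p <- signalParams()
  e1 <- generateEpoch(p, 3, 3, seed = 5)
  e2 <- generateEpoch(p, 3, 3, seed = 5)
  expect_identical(as.numeric(e1), as.numeric(e2))
  # independence across seeds is a property of the noise component (the
  # oscillatory carriers share a frequency, so their correlation is cos of
  # the random phase offset)
  pn <- signalParams(thetaAmpBase = 1e-9, thetaHighAmpBase = 0,
                     gammaAmp = c(slow = 0, fast = 0))
  n1 <- generateEpoch(pn, 0, 5, seed = 5)
  n2 <- generateEpoch(pn, 0, 5, seed = 6)
  expect_lt(abs(cor(as.numeric(n1), as.numeric(n2))), 0.1)
})

test_that("low-theta band power increases strictly with item load (noiseless)", {
  p <- signalParams(noiseScale = 0, gammaAmp = c(slow = 0, fast = 0))
  pow <- vapply(c(1, 3, 5), function(k) {
    e <- generateEpoch(p, k, 4, seed = 7)
    es <- EpochSet(matrix(e), sampleRate = 600, tStart = 0)
    bandPower(es, c(2, 5), c(1, 3))$power
  }, numeric(1))
  expect_true(all(diff(pow) > 0))
  # amplitude rule is linear; the filter's fixed gain cancels in ratios
  amp <- sqrt(pow / pow[1])
  expect_equal(amp, (1 + 0.15 * c(1, 3, 5)) / 1.15, tolerance = 0.02)
})

test_that("measured MVL shrinks with item load as the burst-placement model predicts", {
  p <- signalParams(noiseScale = 0, thetaHighAmpBase = 0,
                    gammaAmp = c(slow = 0, fast = 0.6))
  # dense loads warn that bursts overlap but are still generated
  expect_warning(generateEpoch(p, 5, 2, seed = 1), "overlap")
  mvl <- vapply(1:5, function(k) {
    e <- suppressWarnings(generateEpoch(p, k, 20, seed = 11))
    th <- analyticBandpass(matrix(e), c(2, 5), 600)
    ga <- analyticBandpass(matrix(e), c(70, 140), 600)
    v <- th$valid & ga$valid
    mvlPac(th$phase[v, , drop = FALSE], ga$amplitude[v, , drop = FALSE])
  }, numeric(1))
  expect_true(all(diff(mvl) < 0))
  # oracle: resultant of the placement model = |mean of preferred-phase
  # phasors| x wrapped-normal jitter factor (template factor cancels in
  # the ratio across loads only approximately, so compare the trend)
  placement <- vapply(1:5, function(k) {
    delta <- min(pi / 3, 2 * pi / k)
    phis <- (seq_len(k) - (k + 1) / 2) * delta
    kappa <- max(20 - 3 * k, 0.25)
    Mod(mean(exp(1i * phis))) * exp(-1 / (2 * kappa))
  }, numeric(1))
  expect_gt(cor(mvl, placement), 0.99)
})

test_that("single tight burst per cycle approaches the template's analytic resultant", {
  p <- signalParams(noiseScale = 0, thetaHighAmpBase = 0, thetaAmpSlope = 0,
                    gammaAmp = c(slow = 0.6, fast = 0),
                    couplingBaseKappa = 10, dispersionSlope = 0)
  e <- generateEpoch(p, 1, 30, seed = 5)
  th <- analyticBandpass(matrix(e), c(2, 5), 600)
  ga <- analyticBandpass(matrix(e), c(30, 70), 600)
  v <- th$valid & ga$valid
  mv <- mvlPac(th$phase[v, , drop = FALSE], ga$amplitude[v, , drop = FALSE])
  # numerical integration of the Gaussian burst template against theta
  # phase, times the wrapped-normal jitter resultant
  sigB <- 3 / (6 * 50)
  tt <- seq(-0.125, 0.125, by = 1e-5)
  a <- exp(-tt^2 / (2 * sigB^2))
  rhoT <- Mod(sum(a * exp(2i * pi * 4 * tt))) / sum(a)
  rhoWN <- exp(-(1 / 10) / 2)
  expect_lt(mv, rhoT * rhoWN)            # filter broadening only lowers it
  expect_equal(mv, rhoT * rhoWN, tolerance = 0.07)
})

test_that("the 1/f background slope is recovered across exponents", {
  for (chi in c(0, 1, 2)) {
    p <- signalParams(thetaAmpBase = 1e-9, thetaHighAmpBase = 0,
                      gammaAmp = c(slow = 0, fast = 0), noiseExponent = chi)
    e <- generateEpoch(p, 0, 40, seed = 100 + chi)
    ps <- welchPSD(matrix(e), 600, segLength = 2, range = c(1, 150))
    fit <- lm(log(ps$power) ~ log(ps$freqs))
    expect_equal(unname(-coef(fit)[2]), chi, tolerance = 0.15)
  }
})

test_that("participant generation yields one cue epoch per trial and one move epoch per press", {
  ses <- fixedSession(10)
  p <- signalParams()
  out <- generateParticipant(p, ses, cueWindow = c(-2, 4),
                             moveWindow = c(-1.75, 1.75), seed = 13)
  expect_identical(ncol(out$cue), 10L)
  expect_identical(ncol(out$move), 30L)
  lab <- epochLabels(out$move)
  # steps remaining of press k on an n-step optimal path is n - k + 1
  expect_identical(lab$steps_remaining, rep(c(3L, 2L, 1L), 10))
  expect_identical(sum(lab$final_step), 10L)
  expect_identical(lab$goal_distance, rep(3L, 30))
  # determinism
  out2 <- generateParticipant(p, ses, cueWindow = c(-2, 4),
                              moveWindow = c(-1.75, 1.75), seed = 13)
  expect_identical(signalMatrix(out$move), signalMatrix(out2$move))
  expect_identical(signalMatrix(out$cue), signalMatrix(out2$cue))
  expect_error(generateParticipant(p, new("SessionLog", trials = sessionTrials(ses)[0, ],
                                          side = 4L, experienced = character())),
               "empty session")
})

test_that("steps remaining is recomputed from the current cell on detour paths", {
  ses <- fixedSession(2)
  tr <- sessionTrials(ses)
  tr$path[1] <- "0,0;0,1;0,0;0,1;0,2;0,3"   # backtrack detour
  tr$n_steps[1] <- 5L; tr$tortuosity[1] <- 5 / 3; tr$correct[1] <- FALSE
  ses2 <- new("SessionLog", trials = tr, side = 4L, experienced = ses@experienced)
  mv <- generateParticipant(signalParams(), ses2, events = "move",
                            moveWindow = c(-1.75, 1.75), seed = 3)
  lab <- epochLabels(mv)
  expect_identical(lab$steps_remaining[lab$trial_number == 1], c(3L, 2L, 3L, 2L, 1L))
})

test_that("injected waveform skew is the identity at level 0 and recovers exactly from raw extrema", {
  fs <- 600; tm <- (0:(8 * fs - 1)) / fs
  x <- cos(2 * pi * 3 * tm - pi)
  expect_identical(injectAsymmetry(x, 0, 3, fs), x)
  xs <- injectAsymmetry(x, 0.2, 3, fs)
  ai <- asymmetryIndex(matrix(xs), band = NULL, sampleRate = fs)
  expect_equal(ai$ai, 0.2, tolerance = 0.01)
  # narrowband filtering around the fundamental attenuates the index
  aiNb <- asymmetryIndex(matrix(xs), band = c(2, 5), sampleRate = fs)
  expect_lt(abs(aiNb$ai), abs(ai$ai))
})

test_that("evoked transients are phase-locked: identity at 0, survive averaging, cancel induced phase", {
  ses <- fixedSession(30)
  p <- signalParams(noiseScale = 0.3, gammaAmp = c(slow = 0, fast = 0))
  mv <- generateParticipant(p, ses, events = "move",
                            moveWindow = c(-1, 1), seed = 17)
  expect_identical(signalMatrix(injectEvoked(mv, 0, 0.2, 0.3)),
                   signalMatrix(mv))
  ev <- injectEvoked(mv, amplitude = 2, latency = 0.2, width = 0.3)
  tm <- epochTimes(ev)
  sigE <- 0.3 / 6
  trans <- 2 * exp(-(tm - 0.2)^2 / (2 * sigE^2)) * cos(2 * pi * 4 * (tm - 0.2))
  avg <- rowMeans(signalMatrix(ev))
  # induced theta (random phase) cancels at ~1/sqrt(m); transient survives
  expect_lt(max(abs(avg - trans)), 4 * (1 + 0.15 * 3 + 0.3) / sqrt(30))
  expect_error(injectEvoked(mv, 1, latency = 0.95, width = 0.3), "outside")
})
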