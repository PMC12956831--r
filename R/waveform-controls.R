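# Confound controls: aperiodic (1/f) spectral slope, evoked-response
# amplitude matched across goal distances, and theta waveform asymmetry.

#' Fit the aperiodic (1/f) component of a power spectrum
#'
#' Iterative robust line fit in log-frequency / log-power space: fit a
#' line, flag points lying more than `kMad` scaled median absolute
#' deviations above it as oscillatory peaks, refit excluding them, and
#' repeat until the exclusion set stabilizes (at most `maxIter`
#' iterations). The aperiodic exponent is the negative slope; the offset
#' absorbs any multiplicative scaling of the spectrum. Only the slope is
#' used downstream; no Gaussian peak model is fitted.
#'
#' @param psd a `PSD` from [welchPSD()] (vector power), or a numeric vector
#'   of power values with `freqs` supplied.
#' @param fitRange frequency range (Hz) of the fit.
#' @param freqs frequencies when `psd` is a plain vector.
#' @param kMad peak-exclusion threshold in MADs above the line.
#' @param maxIter iteration cap; non-convergence returns the last fit
#'   flagged `converged = FALSE`.
#' @return list of class `AperiodicFit`: `offset`, `exponent`, `included`
#'   (logical mask over fitted points), `freqs`, `converged`.
#' @export
fitAperiodic <- function(psd, fitRange = c(1, 150), freqs = NULL,
                         kMad = 3, maxIter = 20) {
  if (inherits(psd, "PSD")) { freqs <- psd$freqs; power <- psd$power }
  else power <- psd
  stopifnot(length(freqs) == length(power))
  keep <- freqs >= fitRange[1] & freqs <= fitRange[2] & power > 0
  lf <- log(freqs[keep]); lp <- log(power[keep])
  if (length(lf) < 10L) stop("need >= 10 strictly positive points in range")
  inc <- rep(TRUE, length(lf))
  converged <- FALSE
  lastSlope <- Inf
  for (it in seq_len(maxIter)) {
    fit <- stats::lm.fit(cbind(1, lf[inc]), lp[inc])
    res <- lp - (fit$coefficients[1] + fit$coefficients[2] * lf)
    # floor the spread so an exact power law converges immediately
    spread <- max(stats::mad(res[inc]), 1e-8)
    out <- res > kMad * spread
    # grow each excluded run over its flanks (hysteresis at 1 MAD) so a
    # peak's leakage skirts do not stay in the fit
    flank <- res > spread
    repeat {
      grown <- out | (flank & (c(FALSE, out[-length(out)]) |
                               c(out[-1], FALSE)))
      if (identical(grown, out)) break
      out <- grown
    }
    newInc <- !out
    if (sum(newInc) < 10L) newInc <- inc   # never fit on fewer than 10 points
    if (identical(newInc, inc) ||
        abs(fit$coefficients[2] - lastSlope) < 1e-4) {
      converged <- TRUE
      break
    }
    lastSlope <- fit$coefficients[2]
    inc <- newInc
  }
  if (!converged)
    warning("aperiodic fit did not stabilize in ", maxIter, " iterations")
  structure(list(offset = unname(fit$coefficients[1]),
                 exponent = -unname(fit$coefficients[2]),
                 included = inc, freqs = freqs[keep], converged = converged),
            class = "AperiodicFit")
}

#' Aperiodic exponent versus goal distance
#'
#' For each goal-distance level, averages the per-epoch Welch spectra and
#' fits the aperiodic exponent; then regresses the exponent on distance.
#' A distance-dependent 1/f slope would confound broadband power analyses,
#' so a null slope here is the desired control outcome.
#'
#' @param epochs an [EpochSet-class].
#' @param window analysis window (s).
#' @param distanceLabel label column holding the distance ("steps_remaining"
#'   for move epochs, "goal_distance" for cue epochs).
#' @param fitRange,segLength,kMad passed to [welchPSD()] / [fitAperiodic()].
#' @return list: `slope` (exponent change per step), `exponents`,
#'   `distances`, `fits`.
#' @export
aperiodicVsDistance <- function(epochs, window = c(-1, 1),
                                distanceLabel = "steps_remaining",
                                fitRange = c(1, 150), segLength = 1,
                                kMad = 3) {
  stopifnot(is(epochs, "EpochSet"))
  lab <- epochLabels(epochs)
  dist <- lab[[distanceLabel]]
  levs <- sort(unique(dist))
  if (length(levs) < 2L) stop("need at least 2 distance levels")
  idx <- windowIndex(epochTimes(epochs), window)
  x <- signalMatrix(epochs)[idx, , drop = FALSE]
  psd <- welchPSD(x, sampleRate(epochs), segLength = segLength,
                  range = c(fitRange[1], min(fitRange[2], sampleRate(epochs) / 2)))
  fits <- lapply(levs, function(d) {
    fitAperiodic(rowMeans(psd$power[, dist == d, drop = FALSE]),
                 fitRange = fitRange, freqs = psd$freqs, kMad = kMad)
  })
  expo <- vapply(fits, `[[`, numeric(1), "exponent")
  slope <- unname(stats::coef(stats::lm(expo ~ levs))[2])
  list(slope = slope, exponents = expo, distances = levs, fits = fits)
}

#' Evoked theta amplitude matched across goal distances
#'
#' Quantifies the phase-locked (evoked) component: trials are subsampled to
#' equal counts per goal distance, the raw signals averaged within distance,
#' the average Morlet-transformed, and the band amplitude extracted; the
#' subsampling is repeated `nIter` times and averaged. Distances above
#' `maxDistance` are dropped (few long-path trials), as are distances with
#' fewer than 2 trials (with a warning). Because induced oscillations have
#' random phase across trials they cancel in the average, so this isolates
#' the evoked transient.
#'
#' @param epochs an [EpochSet-class].
#' @param band theta band (Hz).
#' @param window analysis window (s).
#' @param distanceLabel label column holding the distance.
#' @param maxDistance largest distance retained (default 4).
#' @param nIter number of subsampling repetitions.
#' @param nCycles Morlet width.
#' @param seed integer for reproducible subsampling.
#' @return list of class `EvokedProfile`: `profile` (data.frame distance /
#'   amplitude / n_trials), `slope` (amplitude change per step), `nIter`.
#' @export
evokedAmplitudeByDistance <- function(epochs, band = c(2, 5),
                                      window = c(-1, 1),
                                      distanceLabel = "steps_remaining",
                                      maxDistance = 4, nIter = 100,
                                      nCycles = 5, seed = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  lab <- epochLabels(epochs)
  dist <- lab[[distanceLabel]]
  keepLev <- sort(unique(dist[dist <= maxDistance]))
  counts <- vapply(keepLev, function(d) sum(dist == d), integer(1))
  if (any(counts < 2L)) {
    warning("dropping distance level(s) with a single trial: ",
            paste(keepLev[counts < 2L], collapse = ", "))
    keepLev <- keepLev[counts >= 2L]
  }
  if (length(keepLev) < 2L) stop("need >= 2 usable distance levels")
  nSub <- min(vapply(keepLev, function(d) sum(dist == d), integer(1)))
  x <- signalMatrix(epochs)
  fs <- sampleRate(epochs)
  tm <- epochTimes(epochs)
  bandFreqs <- seq(band[1], band[2], length.out = 4)
  amp <- withSeed(seed, {
    acc <- matrix(0, nIter, length(keepLev))
    for (it in seq_len(nIter)) {
      avg <- vapply(keepLev, function(d) {
        pick <- sample(which(dist == d), nSub)
        rowMeans(x[, pick, drop = FALSE])
      }, numeric(nrow(x)))
      tfr <- morletTFR(avg, freqs = bandFreqs, nCycles = nCycles,
                       sampleRate = fs, times = tm)
      tIdx <- windowIndex(tm, window)
      ok <- tfr@valid[, tIdx, drop = FALSE]
      acc[it, ] <- apply(tfr@values[, tIdx, , drop = FALSE], 3L,
                         function(v) mean(sqrt(exp(v[ok]))))
    }
    colMeans(acc)
  })
  profile <- data.frame(distance = keepLev, amplitude = amp, n_trials = nSub)
  slope <- unname(stats::coef(stats::lm(amp ~ keepLev))[2])
  structure(list(profile = profile, slope = slope, nIter = nIter),
            class = "EvokedProfile")
}

# Alternating trough/peak timestamps of one narrowband trace via
# zero-crossing bracketing: exactly one peak between each up- and
# down-crossing and one trough between each down- and up-crossing, which
# prevents noise-induced double extrema. Edge cycles are discarded.
.extremaSequence <- function(x, times) {
  s <- sign(x)
  s[s == 0] <- 1
  up <- which(diff(s) > 0)    # last index before an upward crossing
  down <- which(diff(s) < 0)
  if (length(up) < 2L || length(down) < 1L) return(NULL)
  troughs <- peaks <- numeric(0)
  for (k in seq_len(length(up) - 1L)) {
    d <- down[down > up[k] & down < up[k + 1L]]
    if (length(d) != 1L) next
    pk <- up[k] + which.max(x[(up[k] + 1L):d])
    tr <- d + which.min(x[(d + 1L):up[k + 1L]])
    peaks <- c(peaks, times[pk])
    troughs <- c(troughs, times[tr])
  }
  # leading trough before the first retained peak, if bracketed
  list(peaks = peaks, troughs = troughs)
}

#' Theta waveform asymmetry index
#'
#' Filters each epoch in the theta band with a zero-phase Butterworth
#' filter, identifies alternating extrema by zero-crossing bracketing, and
#' computes the per-cycle asymmetry index: ascending (trough-to-peak) minus
#' descending (peak-to-trough) duration divided by their sum, averaged over
#' cycles. In \[-1, 1\]; zero for a sinusoid; sign flips under time
#' reversal. Defined only when at least `minCycles` full cycles are found
#' (otherwise NA for that epoch). A skewed theta waveform produces harmonic
#' structure that can masquerade as phase-amplitude coupling, which is why
#' this index is tracked against goal distance as a control.
#'
#' Note that waveform skew lives in the harmonics: narrowband filtering
#' (e.g. 2--5 Hz around a 4 Hz rhythm) suppresses them and shrinks the
#' absolute index toward zero, so the filtered AI indexes *relative*
#' asymmetry across conditions rather than the physical duty-cycle ratio.
#' `band = NULL` skips filtering and recovers the raw per-cycle ratio
#' (appropriate for clean, oscillation-dominated signals).
#'
#' @param epochs an [EpochSet-class], or a numeric vector/matrix with
#'   `sampleRate` given.
#' @param band theta band (Hz), or NULL for no filtering.
#' @param window analysis window (s); NULL uses the whole epoch.
#' @param order Butterworth order.
#' @param minCycles minimum full cycles per epoch.
#' @param sampleRate,times for matrix input.
#' @return data.frame: per-epoch labels plus `ai` and `n_cycles`.
#' @export
asymmetryIndex <- function(epochs, band = c(2, 5), window = NULL, order = 3,
                           minCycles = 3, sampleRate = NULL, times = NULL) {
  if (is(epochs, "EpochSet")) {
    x <- signalMatrix(epochs); sampleRate <- sampleRate(epochs)
    times <- epochTimes(epochs); labels <- epochLabels(epochs)
  } else {
    x <- as_matrix(epochs)
    stopifnot(!is.null(sampleRate))
    if (is.null(times)) times <- (seq_len(nrow(x)) - 1L) / sampleRate
    labels <- data.frame(row.names = seq_len(ncol(x)))
  }
  dat <- if (is.null(band)) x else
    as_matrix(bandpassZeroPhase(x, band, sampleRate, family = "butterworth",
                                order = order)$data)
  if (!is.null(window)) {
    idx <- windowIndex(times, window)
    dat <- dat[idx, , drop = FALSE]
    times <- times[idx]
  }
  res <- apply(dat, 2L, function(col) {
    ex <- .extremaSequence(col, times)
    if (is.null(ex)) return(c(NA_real_, 0))
    # cycles: trough_k -> peak_{k+1} -> trough_{k+1}
    ai <- c()
    for (k in seq_len(length(ex$troughs) - 1L)) {
      pk <- ex$peaks[ex$peaks > ex$troughs[k] & ex$peaks < ex$troughs[k + 1L]]
      if (length(pk) != 1L) next
      asc <- pk - ex$troughs[k]
      desc <- ex$troughs[k + 1L] - pk
      ai <- c(ai, (asc - desc) / (asc + desc))
    }
    if (length(ai) < minCycles) c(NA_real_, length(ai))
    else c(mean(ai), length(ai))
  })
  labels$ai <- res[1, ]
  labels$n_cycles <- res[2, ]
  labels
}

#' Waveform asymmetry versus goal distance
#'
#' Per-participant linear regression of the per-epoch asymmetry index on
#' goal distance with trial number as a nuisance regressor (mirroring the
#' coupling regression). A constant asymmetry across distances must yield a
#' null slope; only distance-covarying asymmetry could confound the
#' coupling-distance relationship.
#'
#' @inheritParams asymmetryIndex
#' @param distanceLabel label column holding the distance.
#' @return list: `slope`, `n` (epochs used), `fit` coefficients.
#' @export
asymmetryVsDistance <- function(epochs, band = c(2, 5), window = NULL,
                                distanceLabel = "steps_remaining",
                                order = 3, minCycles = 3) {
  tbl <- asymmetryIndex(epochs, band = band, window = window, order = order,
                        minCycles = minCycles)
  ok <- !is.na(tbl$ai)
  rr <- epochRegression(tbl$ai[ok], tbl[[distanceLabel]][ok],
                        trialNumber = tbl$trial_number[ok])
  list(slope = rr$beta_distance, n = rr$n, fit = rr)
}
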