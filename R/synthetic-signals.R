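# Synthetic virtual-channel signals under the theta-gamma sequence-coding
# model: theta power rises and gamma bursts disperse across the theta cycle
# as the number of maintained sequence items grows.

# Piecewise-linear within-cycle phase warp implementing waveform skew:
# cycle fraction u in [0,1) -> phase psi in [0, 2*pi) such that the
# ascending (trough-to-peak) part occupies a fraction (1+a)/2 of the cycle.
.warpPhase <- function(u, a) {
  if (a == 0) return(2 * pi * u)
  ua <- (1 + a) / 2
  ifelse(u < ua, pi * u / ua, pi + pi * (u - ua) / (1 - ua))
}

# Inverse warp: burst preferred phase psi -> cycle fraction u.
.unwarpPhase <- function(psi, a) {
  psi <- psi %% (2 * pi)
  if (a == 0) return(psi / (2 * pi))
  ua <- (1 + a) / 2
  ifelse(psi < pi, ua * psi / pi, ua + (1 - ua) * (psi - pi) / pi)
}

# Flatten SignalParams for the compiled kernel.
.paramsAsList <- function(p) {
  list(sampleRate = p@sampleRate, thetaFreq = p@thetaFreq,
       thetaAmpBase = p@thetaAmpBase, thetaAmpSlope = p@thetaAmpSlope,
       thetaHighFreq = p@thetaHighFreq, thetaHighAmpBase = p@thetaHighAmpBase,
       thetaHighAmpSlope = p@thetaHighAmpSlope,
       gammaFreqs = unname(p@gammaFreqs[c("slow", "fast")]),
       gammaAmp = unname(p@gammaAmp[c("slow", "fast")]),
       burstWidthCycles = p@burstWidthCycles,
       itemPhaseSpacing = p@itemPhaseSpacing,
       couplingBaseKappa = p@couplingBaseKappa,
       dispersionSlope = p@dispersionSlope,
       noiseExponent = p@noiseExponent, noiseScale = p@noiseScale,
       asymmetry = p@asymmetry, evokedAmp = p@evokedAmp,
       evokedLatency = p@evokedLatency, evokedWidth = p@evokedWidth)
}

# Core builder: one column per epoch, sequence load nItems[e] per epoch.
# Modulation (theta amplitude boost + gamma bursts) applies from time
# `modOnset` onward (-Inf = whole epoch, 0 = cue onset).
.buildEpochs <- function(params, nItems, times, modOnset = -Inf) {
  cppBuildEpochs(.paramsAsList(params), as.integer(nItems), times, modOnset)
}

#' Generate one synthetic epoch
#'
#' A single virtual-channel epoch carrying `nItems` sequence items: theta
#' carrier of amplitude `thetaAmpBase + thetaAmpSlope * nItems`, `nItems`
#' gamma bursts per theta cycle at jittered preferred phases, and 1/f^chi
#' background noise (see [SignalParams-class] for the full model). With
#' `nItems = 0` and `noiseScale = 0` the output is a pure theta sinusoid.
#'
#' @param params a [SignalParams-class].
#' @param nItems number of maintained sequence items (>= 0).
#' @param duration epoch duration (s), at least one theta cycle.
#' @param seed integer; output is reproducible under it.
#' @param tStart epoch start time (s); the time axis is
#'   `tStart + (0:(n-1))/sampleRate`.
#' @return numeric vector with attribute `time`.
#' @export
generateEpoch <- function(params, nItems, duration, seed = NULL, tStart = 0) {
  stopifnot(is(params, "SignalParams"), nItems >= 0)
  if (duration < 1 / params@thetaFreq)
    stop("duration must cover at least one theta cycle")
  if (nItems >= 1 && any(params@gammaAmp > 0) &&
      nItems * params@burstWidthCycles / min(params@gammaFreqs) >
        1 / params@thetaFreq)
    warning("gamma bursts overlap substantially at nItems = ", nItems)
  n <- round(duration * params@sampleRate)
  times <- tStart + (seq_len(n) - 1L) / params@sampleRate
  x <- withSeed(seed, .buildEpochs(params, nItems, times))
  structure(drop(x), time = times)
}

#' Generate a participant's epoch-aligned data from a session
#'
#' Binds task labels to signals: one cue epoch per trial with sequence load
#' equal to the trial's shortest start-to-goal distance (modulation starting
#' at cue onset, t = 0), and one move epoch per button press with load equal
#' to the steps remaining on the shortest path from the current cell
#' (recomputed per step, so the convention also covers detours on incorrect
#' trials). The final press of every trial is labelled `final_step` so
#' downstream analyses can exclude it. Simultaneous-press epochs are never
#' produced by the generator.
#'
#' @param params a [SignalParams-class]; when `paramsNovel` /
#'   `paramsIncorrect` are given, epochs of novel / incorrect trials are
#'   generated with those parameter sets instead (used to build
#'   condition-specific effects; novelty takes precedence).
#' @param session a walked [SessionLog-class].
#' @param events which epoch families to generate.
#' @param cueWindow,moveWindow epoch extents in seconds around the alignment
#'   event (cue onset / button press).
#' @param seed integer for reproducibility.
#' @param paramsNovel,paramsIncorrect optional condition-specific
#'   [SignalParams-class] sets.
#' @return an [EpochSet-class] if one event family is requested, otherwise
#'   a list with elements `cue` and `move`.
#' @export
generateParticipant <- function(params, session, events = c("cue", "move"),
                                cueWindow = c(-5, 8), moveWindow = c(-3, 3),
                                seed = NULL, paramsNovel = NULL,
                                paramsIncorrect = NULL) {
  stopifnot(is(params, "SignalParams"), is(session, "SessionLog"))
  tr <- sessionTrials(session)
  if (nrow(tr) == 0L) stop("empty session")
  if (!"path" %in% names(tr)) stop("session has no chosen paths; run simulateAgent()")
  events <- match.arg(events, several.ok = TRUE)
  fs <- params@sampleRate

  buildSet <- function(labels, window, onset) {
    n <- round(diff(window) * fs)
    times <- window[1] + (seq_len(n) - 1L) / fs
    grp <- rep(1L, nrow(labels))
    if (!is.null(paramsIncorrect)) grp[!labels$correct] <- 3L
    if (!is.null(paramsNovel)) grp[labels$novel] <- 2L
    if (all(grp == 1L)) {
      sig <- .buildEpochs(params, labels$steps_remaining, times, onset)
    } else {
      sig <- matrix(0, n, nrow(labels))
      pset <- list(params, paramsNovel, paramsIncorrect)
      for (g in unique(grp)) {
        sel <- grp == g
        sig[, sel] <- .buildEpochs(pset[[g]], labels$steps_remaining[sel],
                                   times, onset)
      }
    }
    EpochSet(sig, sampleRate = fs, labels = labels, time = times)
  }

  out <- withSeed(seed, {
    res <- list()
    if ("cue" %in% events) {
      lab <- data.frame(
        event_type = "cue", goal_distance = tr$shortest_distance,
        steps_remaining = tr$shortest_distance, correct = tr$correct,
        novel = tr$novel, trial_number = tr$trial_index, final_step = FALSE)
      res$cue <- buildSet(lab, cueWindow, onset = 0)
    }
    if ("move" %in% events) {
      labs <- lapply(seq_len(nrow(tr)), function(t) {
        p <- parsePath(tr$path[t])
        goal <- c(tr$goal_row[t], tr$goal_col[t])
        k <- seq_len(nrow(p) - 1L)
        rem <- abs(p[k, 1] - goal[1]) + abs(p[k, 2] - goal[2])
        data.frame(
          event_type = "move", goal_distance = tr$shortest_distance[t],
          steps_remaining = rem, correct = tr$correct[t], novel = tr$novel[t],
          trial_number = tr$trial_index[t], final_step = k == max(k))
      })
      lab <- do.call(rbind, labs)
      res$move <- buildSet(lab, moveWindow, onset = -Inf)
    }
    res
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Skew the theta waveform of a signal
#'
#' Applies a monotone within-cycle time warp so that ascending and
#' descending phase durations have ratio `(1 + level) / (1 - level)` while
#' the period is preserved. Cycles are anchored to the nominal theta grid
#' starting at the first sample (appropriate for generator output and for
#' testing asymmetry estimators on constructed waves). `level = 0` returns
#' the input unchanged.
#'
#' @param x numeric vector or time-by-epochs matrix.
#' @param level skew in [0, 1); the downstream asymmetry index of a skewed
#'   sinusoid is approximately `level`.
#' @param freq nominal theta frequency (Hz).
#' @param sampleRate sampling rate (Hz).
#' @return object of the same shape as `x`.
#' @export
injectAsymmetry <- function(x, level, freq, sampleRate) {
  stopifnot(level >= 0, level < 1)
  if (level == 0) return(x)
  vec <- !is.matrix(x)
  x <- as_matrix(x)
  n <- nrow(x)
  times <- (seq_len(n) - 1L) / sampleRate
  u <- (freq * times) %% 1
  cyc <- floor(freq * times)
  tau <- (cyc + .warpPhase(u, level) / (2 * pi)) / freq
  out <- apply(x, 2L, function(col)
    stats::approx(times, col, xout = tau, rule = 2)$y)
  out <- as_matrix(out)
  if (vec) drop(out) else out
}

#' Add a phase-locked evoked transient to an EpochSet
#'
#' Adds an identical Gaussian-windowed theta-frequency transient at a fixed
#' post-event latency to every targeted epoch; because the transient is
#' identical across epochs it survives trial averaging (evoked), unlike the
#' generator's induced oscillations whose phase is random per epoch.
#' `amplitude = 0` is the identity.
#'
#' @param epochs an [EpochSet-class].
#' @param amplitude transient peak amplitude (a.u.).
#' @param latency transient centre (s post-event); `latency` +- half
#'   `width` must lie inside the epoch.
#' @param width full width (s), +-3 sd of the Gaussian envelope.
#' @param freq carrier frequency (Hz).
#' @param which integer indices of targeted epochs (default all).
#' @return the modified [EpochSet-class].
#' @export
injectEvoked <- function(epochs, amplitude, latency, width, freq = 4,
                         which = seq_len(ncol(epochs))) {
  stopifnot(is(epochs, "EpochSet"))
  if (amplitude == 0) return(epochs)
  tm <- epochTimes(epochs)
  if (latency - width / 2 < min(tm) || latency + width / 2 > max(tm))
    stop("transient extends outside the epoch")
  sigE <- width / 6
  trans <- amplitude * exp(-(tm - latency)^2 / (2 * sigE^2)) *
    cos(2 * pi * freq * (tm - latency))
  sig <- signalMatrix(epochs)
  sig[, which] <- sig[, which] + trans
  EpochSet(sig, sampleRate = sampleRate(epochs), labels = epochLabels(epochs),
           time = tm)
}
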