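#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom Rcpp evalCpp
#' @useDynLib thetanav, .registration = TRUE
NULL

#' GridMap: the abstract image map
#'
#' A square grid of distinct visual stimuli over which participants navigate.
#' Cells are addressed by 0-based `(row, col)` with row 0 at the top; moves
#' are 4-adjacent (up/down/left/right) and distances are Manhattan.
#'
#' @slot side integer grid side (default task uses 4).
#' @slot stimulusIds character vector of `side^2` distinct stimulus
#'   identifiers, one per cell in row-major order. The assignment is fixed
#'   within a session and randomized between participants.
#' @export
setClass("GridMap", representation(side = "integer", stimulusIds = "character"))

setValidity("GridMap", function(object) {
  if (object@side < 2L) return("side must be >= 2")
  if (length(object@stimulusIds) != object@side^2)
    return("need side^2 stimulus identifiers")
  if (anyDuplicated(object@stimulusIds)) return("stimulus identifiers must be distinct")
  TRUE
})

#' @param side integer grid side.
#' @param stimulusIds optional identifiers; generated (and shuffled under
#'   `seed`) when missing.
#' @param seed optional integer; when given, the stimulus-to-cell assignment
#'   is shuffled reproducibly, emulating per-participant randomization.
#' @rdname GridMap-class
#' @export
gridMap <- function(side = 4L, stimulusIds = NULL, seed = NULL) {
  side <- as.integer(side)
  if (is.null(stimulusIds))
    stimulusIds <- sprintf("stim%02d", seq_len(side^2))
  if (!is.null(seed)) stimulusIds <- withSeed(seed, sample(stimulusIds))
  new("GridMap", side = side, stimulusIds = stimulusIds)
}

#' SessionLog: ordered trial records of one task session
#'
#' Holds the per-trial bookkeeping of one participant's session on the
#' abstract map: start/goal cells, the chosen path (once an agent has walked
#' it), shortest-path distance, tortuosity, correctness, novelty and
#' familiarity, and per-step reaction times. The set of experienced
#' (undirected) cell-pair transitions grows monotonically as paths are
#' walked; novelty of each trial is judged against the history *before*
#' that trial.
#'
#' @slot trials data.frame with one row per trial (see [generateSession()]
#'   and [simulateAgent()] for the columns).
#' @slot side integer grid side.
#' @slot experienced character vector of canonical undirected transition
#'   keys accumulated over the whole session (empty until an agent walks).
#' @export
setClass("SessionLog",
  representation(trials = "data.frame", side = "integer", experienced = "character"))

setValidity("SessionLog", function(object) {
  tr <- object@trials
  need <- c("trial_index", "block", "start_row", "start_col",
            "goal_row", "goal_col", "shortest_distance")
  if (!all(need %in% names(tr))) return("missing required trial columns")
  if (nrow(tr) > 0L) {
    cellsOk <- all(tr$start_row >= 0 & tr$start_row < object@side &
                   tr$goal_row >= 0 & tr$goal_row < object@side &
                   tr$start_col >= 0 & tr$start_col < object@side &
                   tr$goal_col >= 0 & tr$goal_col < object@side)
    if (!cellsOk) return("cells off the grid")
    d <- abs(tr$start_row - tr$goal_row) + abs(tr$start_col - tr$goal_col)
    if (!all(d == tr$shortest_distance))
      return("shortest_distance must equal the Manhattan distance")
    chain <- tr$block[-1] != tr$block[-nrow(tr)] |
      (tr$start_row[-1] == tr$goal_row[-nrow(tr)] &
       tr$start_col[-1] == tr$goal_col[-nrow(tr)])
    if (nrow(tr) > 1L && !all(chain))
      return("within a block, each start must equal the previous goal")
  }
  TRUE
})

#' @param x a SessionLog.
#' @return `sessionTrials` returns the trial data.frame; `nTrials` the number
#'   of trials.
#' @rdname SessionLog-class
#' @export
sessionTrials <- function(x) x@trials

#' @rdname SessionLog-class
#' @export
nTrials <- function(x) nrow(x@trials)

setMethod("show", "SessionLog", function(object) {
  tr <- object@trials
  cat(sprintf("SessionLog: %d trials on a %dx%d grid\n",
              nrow(tr), object@side, object@side))
  if ("correct" %in% names(tr))
    cat(sprintf("  walked: %.1f%% correct, %.1f%% novel paths\n",
                100 * mean(tr$correct), 100 * mean(tr$novel)))
  else cat("  skeleton only (no chosen paths yet)\n")
})

#' EpochSet: epoch-aligned single-channel time series
#'
#' The container every analysis stage consumes: a trials-by-time array of
#' virtual-channel signal with per-epoch labels, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with time samples as rows
#' (rowData column `time`, seconds relative to the alignment event) and
#' epochs as columns (colData = labels). The sampling rate lives in
#' `metadata(x)$sample_rate`.
#'
#' Standard labels written by the generator: `event_type` ("cue" or "move"),
#' `goal_distance` (shortest start-to-goal distance of the trial),
#' `steps_remaining` (shortest distance from the current cell to the goal at
#' the time of the button press; equal to `goal_distance` for cue epochs),
#' `correct`, `novel`, `trial_number`, `final_step`.
#'
#' @export
setClass("EpochSet", contains = "SummarizedExperiment")

setValidity("EpochSet", function(object) {
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    return("EpochSet needs a 'signal' assay")
  if (!"time" %in% names(rowData(object)))
    return("rowData must carry a 'time' column (seconds)")
  fs <- metadata(object)$sample_rate
  if (is.null(fs) || !is.numeric(fs) || fs <= 0)
    return("metadata sample_rate must be a positive number")
  tm <- rowData(object)$time
  if (length(tm) > 1L) {
    dt <- diff(tm)
    if (max(abs(dt - 1 / fs)) > 1e-6 / fs)
      return("time axis must be uniform at 1/sample_rate")
  }
  TRUE
})

#' Construct an EpochSet
#'
#' @param signal numeric matrix, time samples x epochs.
#' @param time numeric vector of sample times (seconds); alternatively give
#'   `tStart` and the axis is built from `sampleRate`.
#' @param sampleRate sampling rate in Hz.
#' @param labels data.frame of per-epoch labels (one row per column of
#'   `signal`).
#' @param tStart epoch start time used when `time` is missing.
#' @return an [EpochSet-class] object.
#' @rdname EpochSet-class
#' @export
EpochSet <- function(signal, sampleRate, labels = NULL, time = NULL, tStart = 0) {
  signal <- as_matrix(signal)
  if (is.null(time)) time <- tStart + (seq_len(nrow(signal)) - 1L) / sampleRate
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(ncol(signal)))
  se <- SummarizedExperiment(
    assays = list(signal = signal),
    rowData = DataFrame(time = time),
    colData = DataFrame(labels, row.names = NULL),
    metadata = list(sample_rate = sampleRate))
  new("EpochSet", se)
}

#' @rdname EpochSet-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname EpochSet-class
#' @export
setMethod("sampleRate", "EpochSet", function(x) metadata(x)$sample_rate)

#' @rdname EpochSet-class
#' @export
epochTimes <- function(x) rowData(x)$time

#' @rdname EpochSet-class
#' @export
signalMatrix <- function(x) unname(assay(x, "signal"))

#' @rdname EpochSet-class
#' @export
epochLabels <- function(x) as.data.frame(colData(x))

#' @rdname EpochSet-class
#' @export
nEpochs <- function(x) ncol(x)

setMethod("show", "EpochSet", function(object) {
  tm <- epochTimes(object)
  cat(sprintf("EpochSet: %d epochs x %d samples @ %g Hz, t = [%.3g, %.3g] s\n",
              ncol(object), nrow(object), sampleRate(object),
              min(tm), max(tm)))
  lb <- epochLabels(object)
  if (ncol(lb)) cat("  labels:", paste(names(lb), collapse = ", "), "\n")
})

#' TFR: time-frequency representation of an EpochSet
#'
#' Log-power (natural log) per epoch, frequency and time from Morlet wavelet
#' convolution, with a validity mask flagging samples within half a wavelet
#' of the epoch edges (these are never allowed into statistics).
#'
#' @slot values numeric array `[frequency, time, epoch]` of log power.
#' @slot freqs analysis frequencies (Hz).
#' @slot times sample times (seconds).
#' @slot labels per-epoch label data.frame carried through from the EpochSet.
#' @slot valid logical `[frequency, time]` mask; FALSE inside edge regions.
#' @slot baselineCorrected logical; TRUE after [baselineCorrect()].
#' @slot baselineWindow numeric length-2 window used for correction (NA
#'   before correction).
#' @slot nCycles Morlet width used.
#' @export
setClass("TFR", representation(
  values = "array", freqs = "numeric", times = "numeric",
  labels = "data.frame", valid = "matrix",
  baselineCorrected = "logical", baselineWindow = "numeric",
  nCycles = "numeric"))

setValidity("TFR", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be [freq, time, epoch]")
  if (d[1] != length(object@freqs) || d[2] != length(object@times))
    return("dims of values must match freqs/times")
  if (!identical(dim(object@valid), d[1:2])) return("valid mask must be [freq, time]")
  TRUE
})

#' @rdname TFR-class
#' @export
tfrValues <- function(x) x@values

#' @rdname TFR-class
#' @export
tfrFreqs <- function(x) x@freqs

#' @rdname TFR-class
#' @export
tfrTimes <- function(x) x@times

setMethod("show", "TFR", function(object) {
  d <- dim(object@values)
  cat(sprintf("TFR: %d freqs (%.3g-%.3g Hz) x %d samples x %d epochs\n",
              d[1], min(object@freqs), max(object@freqs), d[2], d[3]))
  cat(sprintf("  log power, baseline-corrected: %s\n", object@baselineCorrected))
})

#' SignalParams: generative constants of the synthetic signal model
#'
#' Parameters of the theta-gamma sequence-coding generator. A theta carrier
#' of amplitude `thetaAmpBase + thetaAmpSlope * nItems` carries, per cycle,
#' `nItems` Gaussian-windowed gamma bursts placed at equally spaced preferred
#' theta phases spanning an interval of width
#' `min(2*pi, nItems * itemPhaseSpacing)`; each burst's phase is jittered by
#' a wrapped-normal draw with concentration
#' `max(couplingBaseKappa - dispersionSlope * nItems, 0.25)` (variance
#' 1/kappa). Longer sequences therefore raise theta power and disperse gamma
#' across the cycle, lowering phase-amplitude coupling. A 1/f^chi background
#' (exact spectral shaping), optional non-sinusoidal (skewed) theta, and
#' optional phase-locked evoked transients complete the model.
#'
#' @slot sampleRate Hz; must exceed twice the fastest gamma frequency.
#' @slot thetaFreq theta carrier frequency (Hz), inside the 2-5 Hz band.
#' @slot thetaAmpBase,thetaAmpSlope theta amplitude intercept (a.u.) and
#'   change per remaining sequence item.
#' @slot thetaHighFreq,thetaHighAmpBase,thetaHighAmpSlope a second,
#'   high-theta (6-9 Hz) carrier with its own load modulation; it carries no
#'   gamma bursts (the coupling phase band is low theta). Set
#'   `thetaHighAmpBase = 0` to disable.
#' @slot gammaFreqs named c(slow=, fast=) burst carrier frequencies (Hz).
#' @slot gammaAmp named burst peak amplitudes (a.u.).
#' @slot burstWidthCycles burst duration in gamma cycles (+-3 sd of the
#'   Gaussian envelope).
#' @slot itemPhaseSpacing preferred-phase spacing per item (radians).
#' @slot couplingBaseKappa,dispersionSlope burst-phase concentration
#'   intercept and its decrease per item.
#' @slot noiseExponent,noiseScale 1/f^chi exponent and noise standard
#'   deviation (a.u.).
#' @slot asymmetry theta waveform skew in [0, 1): ascending/descending
#'   duration ratio is (1+a)/(1-a).
#' @slot evokedAmp,evokedLatency,evokedWidth phase-locked transient
#'   amplitude (0 disables), latency and full width (s).
#' @export
setClass("SignalParams", representation(
  sampleRate = "numeric", thetaFreq = "numeric",
  thetaAmpBase = "numeric", thetaAmpSlope = "numeric",
  thetaHighFreq = "numeric", thetaHighAmpBase = "numeric",
  thetaHighAmpSlope = "numeric",
  gammaFreqs = "numeric", gammaAmp = "numeric",
  burstWidthCycles = "numeric", itemPhaseSpacing = "numeric",
  couplingBaseKappa = "numeric", dispersionSlope = "numeric",
  noiseExponent = "numeric", noiseScale = "numeric",
  asymmetry = "numeric", evokedAmp = "numeric",
  evokedLatency = "numeric", evokedWidth = "numeric"))

setValidity("SignalParams", function(object) {
  if (object@sampleRate <= 2 * max(object@gammaFreqs))
    return("sampleRate must exceed twice the fastest gamma frequency")
  if (object@thetaAmpBase <= 0) return("thetaAmpBase must be positive")
  if (object@noiseExponent < 0) return("noiseExponent must be >= 0")
  if (object@asymmetry < 0 || object@asymmetry >= 1)
    return("asymmetry must be in [0, 1)")
  if (!all(c("slow", "fast") %in% names(object@gammaFreqs)))
    return("gammaFreqs needs named 'slow' and 'fast' entries")
  TRUE
})

#' @param sampleRate,thetaFreq,thetaAmpBase,thetaAmpSlope,gammaFreqs,gammaAmp
#'   see slots.
#' @param thetaHighFreq,thetaHighAmpBase,thetaHighAmpSlope see slots.
#' @param burstWidthCycles,itemPhaseSpacing,couplingBaseKappa,dispersionSlope
#'   see slots.
#' @param noiseExponent,noiseScale,asymmetry,evokedAmp,evokedLatency,evokedWidth
#'   see slots.
#' @rdname SignalParams-class
#' @export
signalParams <- function(sampleRate = 600, thetaFreq = 4,
                         thetaAmpBase = 1, thetaAmpSlope = 0.15,
                         thetaHighFreq = 7.5, thetaHighAmpBase = 0.5,
                         thetaHighAmpSlope = 0.075,
                         gammaFreqs = c(slow = 50, fast = 100),
                         gammaAmp = c(slow = 0.6, fast = 0.6),
                         burstWidthCycles = 3, itemPhaseSpacing = pi / 3,
                         couplingBaseKappa = 20, dispersionSlope = 3,
                         noiseExponent = 1, noiseScale = 1,
                         asymmetry = 0, evokedAmp = 0,
                         evokedLatency = 0.3, evokedWidth = 0.4) {
  new("SignalParams", sampleRate = sampleRate, thetaFreq = thetaFreq,
      thetaAmpBase = thetaAmpBase, thetaAmpSlope = thetaAmpSlope,
      thetaHighFreq = thetaHighFreq, thetaHighAmpBase = thetaHighAmpBase,
      thetaHighAmpSlope = thetaHighAmpSlope,
      gammaFreqs = gammaFreqs, gammaAmp = gammaAmp,
      burstWidthCycles = burstWidthCycles, itemPhaseSpacing = itemPhaseSpacing,
      couplingBaseKappa = couplingBaseKappa, dispersionSlope = dispersionSlope,
      noiseExponent = noiseExponent, noiseScale = noiseScale,
      asymmetry = asymmetry, evokedAmp = evokedAmp,
      evokedLatency = evokedLatency, evokedWidth = evokedWidth)
}

setMethod("show", "SignalParams", function(object) {
  cat(sprintf(paste0(
    "SignalParams: fs = %g Hz, theta %g Hz (amp %g + %g/item, asym %g)\n",
    "  gamma slow/fast %g/%g Hz; kappa %g - %g/item, item spacing %.3g rad\n",
    "  1/f^%g noise (sd %g), evoked amp %g\n"),
    object@sampleRate, object@thetaFreq, object@thetaAmpBase,
    object@thetaAmpSlope, object@asymmetry,
    object@gammaFreqs["slow"], object@gammaFreqs["fast"],
    object@couplingBaseKappa, object@dispersionSlope, object@itemPhaseSpacing,
    object@noiseExponent, object@noiseScale, object@evokedAmp))
})
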