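# Theta-gamma phase-amplitude coupling: zero-phase narrowband filtering,
# analytic signal, amplitude-weighted mean vector length, and the GLM
# residualization that removes trial-wise power confounds.

# Windowed-sinc (Hamming) band-pass FIR; odd length covering `cycles`
# cycles of the band's low edge.
.firBandpass <- function(band, sampleRate, cycles = 3) {
  stopifnot(band[1] > 0, band[2] < sampleRate / 2, band[1] < band[2])
  L <- round(cycles / band[1] * sampleRate)
  if (L %% 2 == 0) L <- L + 1L
  signal::fir1(L - 1L, band / (sampleRate / 2), type = "pass")
}

#' Zero-phase band-pass filtering
#'
#' Forward-backward (zero net phase) band-pass filtering of each epoch.
#' The default FIR family is a windowed-sinc design of odd length spanning
#' three cycles of the band's low edge, applied via its exact
#' forward-backward magnitude response; "butterworth" applies
#' [signal::filtfilt()] with a Butterworth design of the given order. Half
#' a filter length at each end of every epoch is flagged invalid.
#'
#' @param x numeric vector or time-by-epochs matrix.
#' @param band `c(lo, hi)` in Hz, inside (0, Nyquist).
#' @param sampleRate sampling rate (Hz).
#' @param family "fir" or "butterworth".
#' @param order Butterworth order.
#' @param cycles FIR length in cycles of the band's low edge.
#' @return list of class `FilteredSignal`: `data` (same shape as `x`),
#'   `valid` (per-sample logical mask), `band`, `sampleRate`, `family`.
#' @export
bandpassZeroPhase <- function(x, band, sampleRate,
                              family = c("fir", "butterworth"),
                              order = 4, cycles = 3) {
  family <- match.arg(family)
  vec <- !is.matrix(x)
  x <- as_matrix(x)
  taps <- .firBandpass(band, sampleRate, cycles)
  L <- length(taps)
  if (nrow(x) <= L + 2L)
    stop("epoch (", nrow(x), " samples) leaves no valid samples after ",
         "masking the filter edges (length ", L, "); band ", band[1], "-",
         band[2], " Hz needs longer epochs")
  y <- if (family == "fir") {
    .zeroPhaseFilterFFT(x, taps)
  } else {
    # zero-phase Butterworth: apply |H(w)|^2 (the exact forward-backward
    # magnitude response) in the frequency domain; the IIR ringing decays
    # well inside the masked edge region
    bt <- signal::butter(order, band / (sampleRate / 2), type = "pass")
    nfft <- nextFastLen(nrow(x) + L)
    ew <- exp(-2i * pi * outer((seq_len(nfft) - 1L) / nfft,
                               seq_along(bt$b) - 1L))
    H <- drop(ew %*% bt$b) / drop(ew[, seq_along(bt$a), drop = FALSE] %*% bt$a)
    Re(.ifft(.padFFT(x, nfft) * Mod(H)^2))[seq_len(nrow(x)), , drop = FALSE]
  }
  y <- as_matrix(y)
  half <- ceiling(L / 2)
  valid <- rep(TRUE, nrow(x))
  valid[c(seq_len(min(half, nrow(x))),
          seq.int(max(nrow(x) - half + 1L, 1L), nrow(x)))] <- FALSE
  structure(list(data = if (vec) drop(y) else y, valid = valid, band = band,
                 sampleRate = sampleRate, family = family),
            class = "FilteredSignal")
}

#' Analytic signal (instantaneous phase and amplitude)
#'
#' Hilbert-transform analytic extension of a (filtered) narrowband signal:
#' phase is the argument in (-pi, pi], amplitude the modulus. For
#' `A * sin(2*pi*f*t)` the amplitude is approximately `A` on valid samples
#' and the phase advances `2*pi*f` per second.
#'
#' @param x a `FilteredSignal` from [bandpassZeroPhase()], or a numeric
#'   vector/matrix of already-narrowband data.
#' @return list of class `AnalyticPair`: `phase`, `amplitude` (same shape
#'   as the input data), `valid`.
#' @export
analyticSignal <- function(x) {
  if (inherits(x, "FilteredSignal")) {
    dat <- as_matrix(x$data); valid <- x$valid
  } else {
    dat <- as_matrix(x); valid <- rep(TRUE, nrow(dat))
  }
  if (all(dat == 0)) stop("all-zero (or fully masked) input: phase undefined")
  z <- .hilbertFFT(dat)
  structure(list(phase = Arg(z), amplitude = Mod(z), valid = valid),
            class = "AnalyticPair")
}

# Several analytic band-passes sharing one forward FFT of the epoch
# matrix: for each band in the named list, the complex analytic narrowband
# signal (`z`) and the per-sample valid mask. The pipeline's hot path.
.analyticBands <- function(x, bands, sampleRate, cycles = 3) {
  x <- as_matrix(x)
  n <- nrow(x)
  taps <- lapply(bands, .firBandpass, sampleRate = sampleRate, cycles = cycles)
  Ls <- lengths(taps)
  nfft <- nextFastLen(n + max(Ls))
  X <- .padFFT(x, nfft)
  u <- .analyticWeights(nfft)
  out <- lapply(seq_along(bands), function(i) {
    G <- Mod(stats::fft(c(taps[[i]], numeric(nfft - Ls[i]))))^2 * u
    z <- .ifft(X * G)[seq_len(n), , drop = FALSE]
    half <- ceiling(Ls[i] / 2)
    valid <- rep(TRUE, n)
    valid[c(seq_len(min(half, n)), seq.int(max(n - half + 1L, 1L), n))] <- FALSE
    list(z = z, valid = valid)
  })
  names(out) <- names(bands)
  out
}

#' One-step analytic band-pass
#'
#' Fuses [bandpassZeroPhase()] (FIR family) and [analyticSignal()] into a
#' single frequency-domain operation: the real part equals the zero-phase
#' filtered signal exactly on valid samples, and phase/amplitude agree with
#' the sequential route away from the masked edges. This is the form the
#' pipeline uses on large epoch matrices.
#'
#' @inheritParams bandpassZeroPhase
#' @return an `AnalyticPair` (see [analyticSignal()]).
#' @export
analyticBandpass <- function(x, band, sampleRate, cycles = 3) {
  ab <- .analyticBands(x, list(b = band), sampleRate, cycles)$b
  structure(list(phase = Arg(ab$z), amplitude = Mod(ab$z), valid = ab$valid),
            class = "AnalyticPair")
}

#' Mean vector length phase-amplitude coupling
#'
#' The amplitude-weighted resultant of the phase series:
#' `MVL = |sum(a * exp(1i*phi))| / sum(a)` over valid samples (normalized
#' form, bounded in [0, 1] and invariant to amplitude scaling and global
#' phase rotation). The unnormalized variant `|mean(a * exp(1i*phi))|` is
#' also available; the normalized form is the primary estimator and the
#' power residualization handles remaining power leakage.
#'
#' @param phase,amplitude numeric vectors or time-by-epochs matrices
#'   (theta phase and gamma amplitude).
#' @param valid optional logical per-sample mask (e.g. filter edges).
#' @param normalize divide by the summed amplitude (default) rather than
#'   the sample count.
#' @return scalar (vector input) or per-epoch numeric vector.
#' @export
mvlPac <- function(phase, amplitude, valid = NULL, normalize = TRUE) {
  phase <- as_matrix(phase); amplitude <- as_matrix(amplitude)
  stopifnot(identical(dim(phase), dim(amplitude)))
  if (!is.null(valid)) {
    phase <- phase[valid, , drop = FALSE]
    amplitude <- amplitude[valid, , drop = FALSE]
  }
  sums <- colSums(amplitude)
  if (any(sums == 0)) stop("summed amplitude is zero: MVL undefined")
  vec <- Mod(colSums(amplitude * exp(1i * phase)))
  out <- if (normalize) vec / sums else vec / nrow(amplitude)
  drop(out)
}

#' Per-epoch PAC table
#'
#' Computes, for every epoch, the raw theta-gamma mean vector length
#' together with the raw (uncorrected) theta and gamma band powers from the
#' same window -- the covariates the residualization GLM uses. Labels are
#' carried through.
#'
#' @param epochs an [EpochSet-class].
#' @param thetaBand,gammaBand frequency bands (Hz).
#' @param window analysis window (s): the 0--3 s cue period or the
#'   \[-1, 1\] s window around each button press.
#' @param normalize MVL normalization (see [mvlPac()]).
#' @param cycles FIR length in low-edge cycles.
#' @return data.frame: labels + `raw_mvl`, `raw_mvl_unnorm`, `theta_power`,
#'   `gamma_power`.
#' @export
pacTable <- function(epochs, thetaBand = c(2, 5), gammaBand = c(70, 140),
                     window = c(-1, 1), normalize = TRUE, cycles = 3) {
  stopifnot(is(epochs, "EpochSet"))
  x <- signalMatrix(epochs)
  fs <- sampleRate(epochs)
  th <- analyticBandpass(x, thetaBand, fs, cycles)
  ga <- analyticBandpass(x, gammaBand, fs, cycles)
  idx <- intersect(windowIndex(epochTimes(epochs), window),
                   which(th$valid & ga$valid))
  if (length(idx) < 5 * fs / mean(thetaBand))
    stop("window too short: need at least 5 cycles of the phase band")
  ph <- th$phase[idx, , drop = FALSE]
  am <- ga$amplitude[idx, , drop = FALSE]
  out <- epochLabels(epochs)
  out$raw_mvl <- mvlPac(ph, am, normalize = TRUE)
  out$raw_mvl_unnorm <- mvlPac(ph, am, normalize = FALSE)
  out$theta_power <- colMeans(th$amplitude[idx, , drop = FALSE]^2) / 2
  out$gamma_power <- colMeans(am^2) / 2
  if (!normalize) out$raw_mvl <- out$raw_mvl_unnorm
  out
}

#' Residualize PAC against trial-wise power
#'
#' Ordinary least squares of the raw per-epoch MVL on an intercept plus
#' theta and gamma power for one participant; `residual_pac` is observed
#' minus fitted, hence zero-mean and orthogonal to both power covariates by
#' construction. If the power columns are collinear the gamma column is
#' dropped with a warning.
#'
#' @param table a data.frame from [pacTable()] (columns `raw_mvl`,
#'   `theta_power`, `gamma_power`).
#' @return the table with a `residual_pac` column appended.
#' @export
residualizePac <- function(table) {
  need <- c("raw_mvl", "theta_power", "gamma_power")
  stopifnot(all(need %in% names(table)))
  if (nrow(table) < 6L)
    stop("need at least 3 more epochs than regressors (6)")
  X <- cbind(1, table$theta_power, table$gamma_power)
  if (qr(X)$rank < 3L) {
    warning("theta and gamma power are collinear; dropping gamma power")
    fit <- stats::lm(raw_mvl ~ theta_power, data = table)
  } else {
    fit <- stats::lm(raw_mvl ~ theta_power + gamma_power, data = table)
  }
  table$residual_pac <- unname(stats::residuals(fit))
  table
}
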