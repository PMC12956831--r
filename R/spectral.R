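# Time-frequency power estimation: Morlet wavelet transform, log transform,
# baseline correction, band power and Welch spectral density.

# Complex Morlet kernel at frequency f: complex exponential under a Gaussian
# with sigma_t = nCycles / (2*pi*f), L2-normalized, truncated at +-3 sigma.
.morletKernel <- function(f, sampleRate, nCycles) {
  sigma <- nCycles / (2 * pi * f)
  half <- ceiling(3 * sigma * sampleRate)
  t <- (-half:half) / sampleRate
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma^2))
  k / sqrt(sum(Mod(k)^2) / sampleRate)
}

#' Morlet wavelet time-frequency representation
#'
#' Convolves each epoch with five-cycle complex Morlet wavelets on a
#' 20-point log-spaced 1--30 Hz grid (defaults), squares the magnitude and
#' takes the natural log. Samples within half a wavelet support of either
#' epoch edge are flagged invalid per frequency and must not enter
#' statistics; [baselineCorrect()] enforces this.
#'
#' @param epochs an [EpochSet-class] (or a plain time-by-epochs matrix,
#'   in which case `sampleRate` must be given).
#' @param freqs analysis frequencies (Hz).
#' @param nCycles wavelet width in cycles.
#' @param sampleRate,times used only for matrix input.
#' @return a [TFR-class] of uncorrected log power.
#' @export
morletTFR <- function(epochs, freqs = logSpace(1, 30, 20), nCycles = 5,
                      sampleRate = NULL, times = NULL) {
  if (is(epochs, "EpochSet")) {
    x <- signalMatrix(epochs)
    sampleRate <- sampleRate(epochs)
    times <- epochTimes(epochs)
    labels <- epochLabels(epochs)
  } else {
    x <- as_matrix(epochs)
    stopifnot(!is.null(sampleRate))
    if (is.null(times)) times <- (seq_len(nrow(x)) - 1L) / sampleRate
    labels <- data.frame(row.names = seq_len(ncol(x)))
  }
  n <- nrow(x); m <- ncol(x)
  kernels <- lapply(freqs, .morletKernel, sampleRate = sampleRate,
                    nCycles = nCycles)
  lens <- lengths(kernels)
  tooLong <- lens > n
  if (any(tooLong))
    stop("epoch too short for a ", nCycles, "-cycle wavelet at ",
         paste(signif(freqs[tooLong], 3), collapse = ", "), " Hz")
  nfft <- nextFastLen(n + max(lens))
  X <- .padFFT(x, nfft)
  vals <- array(NA_real_, c(length(freqs), n, m))
  valid <- matrix(TRUE, length(freqs), n)
  for (i in seq_along(freqs)) {
    k <- kernels[[i]]
    half <- (lens[i] - 1L) / 2L
    kv <- complex(length.out = nfft)
    kv[seq_len(half + 1L)] <- k[(half + 1L):lens[i]]
    kv[(nfft - half + 1L):nfft] <- k[seq_len(half)]
    W <- .ifft(X * stats::fft(kv))[seq_len(n), , drop = FALSE]
    vals[i, , ] <- log(Mod(W)^2)
    edge <- half   # half a wavelet support at each end
    if (edge > 0) valid[i, c(seq_len(min(edge, n)),
                             seq.int(max(n - edge + 1L, 1L), n))] <- FALSE
  }
  new("TFR", values = vals, freqs = freqs, times = times, labels = labels,
      valid = valid, baselineCorrected = FALSE, baselineWindow = c(NA_real_, NA_real_),
      nCycles = nCycles)
}

#' Baseline-correct a log-power TFR
#'
#' Subtracts, per frequency and epoch, the mean log power in the baseline
#' window, then crops to the analysis window. Mode defaults follow the task
#' conventions: cue epochs are corrected against \[-1.5, -0.5\] s before cue
#' onset and cropped to the 0--3 s cue period; move epochs against
#' \[-1, -0.5\] s before the button press and cropped to \[-1, 1\] s. The
#' baseline window must lie outside every frequency's invalid edge region.
#'
#' @param tfr a [TFR-class].
#' @param mode "cue" or "move"; sets default windows.
#' @param baseline,crop explicit windows (s) overriding the mode defaults;
#'   `crop = NULL` disables cropping.
#' @return the corrected (and cropped) [TFR-class].
#' @export
baselineCorrect <- function(tfr, mode = c("cue", "move"), baseline = NULL,
                            crop) {
  stopifnot(is(tfr, "TFR"))
  mode <- match.arg(mode)
  if (is.null(baseline))
    baseline <- if (mode == "cue") c(-1.5, -0.5) else c(-1, -0.5)
  if (missing(crop))
    crop <- if (mode == "cue") c(0, 3) else c(-1, 1)
  bIdx <- windowIndex(tfr@times, baseline)
  if (!all(tfr@valid[, bIdx]))
    stop("baseline window overlaps wavelet edge regions; use longer epochs")
  vals <- tfr@values
  base <- apply(vals[, bIdx, , drop = FALSE], c(1L, 3L), mean)
  vals <- sweep(vals, c(1L, 3L), base, "-")
  times <- tfr@times
  valid <- tfr@valid
  if (!is.null(crop)) {
    cIdx <- windowIndex(times, crop)
    vals <- vals[, cIdx, , drop = FALSE]
    valid <- valid[, cIdx, drop = FALSE]
    times <- times[cIdx]
  }
  new("TFR", values = vals, freqs = tfr@freqs, times = times,
      labels = tfr@labels, valid = valid, baselineCorrected = TRUE,
      baselineWindow = baseline, nCycles = tfr@nCycles)
}

#' Per-epoch band power
#'
#' For a [TFR-class]: the mean of the (log, possibly baseline-corrected)
#' power over the band's frequencies (closed interval) and the window's
#' valid samples. For an [EpochSet-class]: raw (never baseline-corrected)
#' band power as the mean square of the zero-phase band-passed signal over
#' the window -- the convention used for regression covariates and
#' predictors, where power estimates are deliberately left uncorrected.
#'
#' @param x a [TFR-class] or [EpochSet-class].
#' @param band numeric `c(lo, hi)` in Hz; a computed frequency belongs to
#'   the band when it lies in the closed interval.
#' @param window numeric `c(t0, t1)` in seconds.
#' @param ... passed to the band-pass filter for EpochSet input.
#' @return data.frame: per-epoch labels plus a `power` column; attributes
#'   `band` and `corrected` record what was computed.
#' @export
setGeneric("bandPower", function(x, band, window, ...) standardGeneric("bandPower"))

#' @rdname bandPower
#' @export
setMethod("bandPower", "TFR", function(x, band, window, ...) {
  fIdx <- which(x@freqs >= band[1] & x@freqs <= band[2])
  if (length(fIdx) == 0L) stop("band contains no computed frequency")
  tIdx <- windowIndex(x@times, window)
  ok <- x@valid[fIdx, tIdx, drop = FALSE]
  if (!any(ok)) stop("window contains no valid samples in this band")
  vals <- x@values[fIdx, tIdx, , drop = FALSE]
  pow <- apply(vals, 3L, function(v) mean(v[ok]))
  out <- x@labels
  if (nrow(out) != length(pow)) out <- data.frame(row.names = seq_along(pow))
  out$power <- pow
  attr(out, "band") <- band
  attr(out, "corrected") <- x@baselineCorrected
  out
})

#' @rdname bandPower
#' @export
setMethod("bandPower", "EpochSet", function(x, band, window, ...) {
  ab <- analyticBandpass(signalMatrix(x), band, sampleRate(x), ...)
  idx <- intersect(windowIndex(epochTimes(x), window), which(ab$valid))
  if (length(idx) == 0L) stop("window contains no valid (filter-safe) samples")
  pow <- colMeans(ab$amplitude[idx, , drop = FALSE]^2) / 2
  out <- epochLabels(x)
  out$power <- pow
  attr(out, "band") <- band
  attr(out, "corrected") <- FALSE
  out
})

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-tapered, 50%-overlapping segments;
#' one-sided density normalized so that the integral of the PSD over
#' frequency equals the signal variance (Parseval).
#'
#' @param x numeric vector or time-by-epochs matrix.
#' @param sampleRate sampling rate (Hz).
#' @param segLength segment length in seconds (default 1 s).
#' @param overlap fractional overlap between segments.
#' @param range frequency range (Hz) retained in the output.
#' @return list of class `PSD`: `freqs` (Hz) and `power` (density; a vector
#'   for vector input, frequencies-by-epochs matrix otherwise).
#' @export
welchPSD <- function(x, sampleRate, segLength = 1, overlap = 0.5,
                     range = c(1, 150)) {
  vec <- !is.matrix(x)
  x <- as_matrix(x)
  n <- nrow(x)
  nseg <- round(segLength * sampleRate)
  step <- max(1L, round(nseg * (1 - overlap)))
  if (n < nseg + step)
    stop("epoch too short for Welch estimation: need >= 2 segments of ",
         nseg, " samples")
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- hannWindow(nseg)
  U <- sum(w^2)
  acc <- matrix(0, floor(nseg / 2) + 1L, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L), , drop = FALSE] * w
    S <- Mod(stats::mvfft(seg))^2
    acc <- acc + S[seq_len(nrow(acc)), , drop = FALSE]
  }
  acc <- acc / length(starts)
  scale <- 1 / (sampleRate * U)
  pxx <- acc * scale
  # one-sided: double everything except DC (and Nyquist for even nseg)
  dbl <- rep(2, nrow(pxx)); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[length(dbl)] <- 1
  pxx <- pxx * dbl
  freqs <- (seq_len(nrow(pxx)) - 1L) * sampleRate / nseg
  keep <- freqs >= range[1] & freqs <= range[2]
  out <- list(freqs = freqs[keep],
              power = if (vec) drop(pxx[keep, , drop = FALSE])
                      else pxx[keep, , drop = FALSE])
  class(out) <- "PSD"
  out
}
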