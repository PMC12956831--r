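# Internal numerical helpers shared across modules.

#' Logarithmically spaced grid
#'
#' `logSpace(a, b, n)` returns `n` points exactly log-spaced between `a` and
#' `b`, endpoints included. Used for the default 20-point 1--30 Hz
#' time-frequency grid.
#'
#' @param from,to positive endpoints (included).
#' @param n number of points.
#' @return numeric vector of length `n`.
#' @export
logSpace <- function(from, to, n) {
  stopifnot(from > 0, to > 0, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

# Next 5-smooth integer >= n; keeps FFT lengths fast.
nextFastLen <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Periodic Hann window.
hannWindow <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed.
subSeeds <- function(seed, k) withSeed(seed, sample.int(.Machine$integer.max - 1L, k))

as_matrix <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1L)

# Column-wise FFT of x zero-padded to nfft rows.
.padFFT <- function(x, nfft) {
  x <- as_matrix(x)
  stats::mvfft(rbind(x, matrix(0, nfft - nrow(x), ncol(x))))
}

.ifft <- function(X) stats::mvfft(X, inverse = TRUE) / nrow(X)

# One-sided spectral weights that turn an inverse FFT into the analytic
# signal (2x positive frequencies, DC/Nyquist kept, negatives zeroed).
.analyticWeights <- function(nfft) {
  u <- numeric(nfft)
  half <- floor(nfft / 2)
  u[1] <- 1
  if (nfft %% 2 == 0) {
    u[2:half] <- 2
    u[half + 1] <- 1
  } else {
    u[2:(half + 1)] <- 2
  }
  u
}

# Zero-phase filtering of each column of x with a linear-phase FIR given by
# `taps`: frequency-domain multiplication by |H(w)|^2, i.e. the exact
# forward-backward (filtfilt) magnitude response with no group delay. The
# effective (autocorrelation) kernel spans +-(L-1) samples, so padding to
# n + L - 1 already yields the exact linear convolution at every output
# sample. analytic = TRUE additionally applies the Hilbert one-sided
# weights so the output is the complex analytic narrowband signal.
.zeroPhaseFilterFFT <- function(x, taps, analytic = FALSE) {
  x <- as_matrix(x)
  n <- nrow(x)
  L <- length(taps)
  nfft <- nextFastLen(n + L)
  H <- stats::fft(c(taps, numeric(nfft - L)))
  G <- Mod(H)^2
  if (analytic) G <- G * .analyticWeights(nfft)
  Y <- .ifft(.padFFT(x, nfft) * G)[seq_len(n), , drop = FALSE]
  if (analytic) Y else Re(Y)
}

# Analytic (complex) signal of each column via the FFT method. No filtering.
.hilbertFFT <- function(x) {
  x <- as_matrix(x)
  .ifft(stats::mvfft(x) * .analyticWeights(nrow(x)))
}

# Sample index range (inclusive) covered by a [t0, t1] window on `times`.
windowIndex <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0L)
    stop("window [", window[1], ", ", window[2], "] selects no samples")
  idx
}
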