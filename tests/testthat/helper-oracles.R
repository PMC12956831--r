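# Independent oracles and fixture builders used across the suite.

# Brute-force recursive count of monotone lattice paths between two cells;
# independent of both the package's binomial formula and its DFS
# enumeration.
oracleCountPaths <- function(a, b) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(1L)
    (if (i > 0) rec(i - 1, j) else 0L) + (if (j > 0) rec(i, j - 1) else 0L)
  }
  rec(abs(a[1] - b[1]), abs(a[2] - b[2]))
}

# All cells of a side x side grid as a 2-column matrix (0-based).
gridCells <- function(side) as.matrix(expand.grid(0:(side - 1), 0:(side - 1)))

# EpochSet holding m identical (or phase-jittered) sinusoidal epochs.
sineEpochs <- function(freq, duration, sampleRate = 600, amplitude = 1,
                       m = 1, phases = rep(0, m), tStart = 0,
                       labels = NULL) {
  n <- round(duration * sampleRate)
  tm <- tStart + (seq_len(n) - 1) / sampleRate
  sig <- vapply(phases, function(ph) amplitude * sin(2 * pi * freq * tm + ph),
                numeric(n))
  EpochSet(sig, sampleRate = sampleRate, labels = labels, time = tm)
}

# A walked all-correct session with fixed-distance trials, built by hand.
fixedSession <- function(nTrials, distance = 3) {
  stopifnot(distance == 3)
  path <- "0,0;0,1;0,2;0,3"; back <- "0,3;0,2;0,1;0,0"
  trials <- data.frame(
    trial_index = seq_len(nTrials), block = 1L,
    start_row = 0L, start_col = rep(c(0L, 3L), length.out = nTrials),
    goal_row = 0L, goal_col = rep(c(3L, 0L), length.out = nTrials))
  trials$shortest_distance <- 3L
  trials$path <- rep(c(path, back), length.out = nTrials)
  trials$n_steps <- 3L
  trials$tortuosity <- 1
  trials$correct <- TRUE
  trials$novel <- c(TRUE, rep(FALSE, nTrials - 1))
  trials$familiarity <- c(0, rep(1, nTrials - 1))
  trials$step_times <- "0.4;0.4;0.4"
  new("SessionLog", trials = trials, side = 4L,
      experienced = c("0,0|0,1", "0,1|0,2", "0,2|0,3"))
}

# Null generator: no distance modulation of anything (flat theta, no
# bursts, symmetric waveform, fixed 1/f exponent).
nullParams <- function(...) {
  signalParams(thetaAmpSlope = 0, thetaHighAmpSlope = 0,
               gammaAmp = c(slow = 0, fast = 0), ...)
}
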