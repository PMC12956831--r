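---
title: "Theta-gamma coupling analysis of goal-directed navigation: models and methods"
author: "thetanav maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-gamma coupling analysis of goal-directed navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

During goal-directed navigation the brain must construct, hold, and execute
a sequence of upcoming locations. A long-standing proposal from the working
memory literature is that such sequences are carried by **theta-gamma
phase-amplitude coupling (PAC)**: each item in the sequence is represented
by a burst of gamma-band activity at a distinct phase of the slower theta
rhythm. Two quantitative predictions follow:

* **theta power should increase with sequence length** (more items require a
  longer usable cycle, reflected in carrier amplitude), and
* **PAC should decrease with sequence length**, because gamma bursts become
  more widely dispersed across the theta cycle.

In an abstract navigation task -- a 4x4 grid of images where each trial asks
for the shortest path from a start to a goal location -- "sequence length"
is the number of steps remaining to the goal. `thetanav` implements the
full analysis chain for epoch-aligned virtual-channel time series from such
tasks: Morlet time-frequency power, theta band power, mean-vector-length
PAC with trial-wise power residualization, trial-wise regressions on goal
distance with group-level t-tests, and the three standard confound controls
(aperiodic 1/f slope, evoked-response amplitude, theta waveform asymmetry).
It also implements the task itself (`generateSession()`, `simulateAgent()`)
and a generative signal model (`signalParams()`, `generateParticipant()`),
so the entire chain can be validated by parameter recovery with no external
data.

# The task model

Cells are 0-based `(row, col)` pairs with 4-adjacency; distances are
Manhattan, matching the up/down/left/right moves. Goals are drawn uniformly
from all cells at least three steps from the start, and each trial starts
at the previous goal (blocks restart the chain with a random cell; the
task description is silent on block boundaries, and independent blocks are
the conservative choice). On the 4x4 grid this admits 124 ordered
start-goal pairs carrying 592 distinct shortest paths in total
(`enumerateValidPairs()`; the counts are `choose(d, |drow|)` and are
cross-checked against exhaustive enumeration in the test suite).

Behavioural bookkeeping follows the task's conventions: *tortuosity* is
steps taken over shortest distance (1 for correct trials), a path is
*novel* when at least one of its undirected transitions has never been
walked in either direction, and *familiarity* is the fraction of its
transitions previously experienced. The simulated agent walks a uniformly
drawn shortest path with probability `pCorrect` (default 0.85, a typical
accuracy for this task family) and otherwise inserts a backtrack detour.
Per-step reaction times are log-normal plumbing with no analysis riding on
them.

# The generative signal model

`generateEpoch()` synthesizes one epoch carrying `nItems` sequence items at
`sampleRate` 600 Hz (the acquisition rate of typical MEG systems):

* **Theta carrier.** A 4 Hz sinusoid (inside the 2-5 Hz "low theta" band)
  with amplitude `thetaAmpBase + thetaAmpSlope * nItems`. A second,
  burst-free carrier at 7.5 Hz mirrors the load effect in the 6-9 Hz
  "high theta" band at half the amplitude. For cue epochs the amplitude
  boost starts at cue onset; move epochs are stationary within the epoch.
* **Gamma bursts.** Per theta cycle, `nItems` Gaussian-windowed burst
  packets of the band carrier (slow 50 Hz, fast 100 Hz; three gamma cycles
  wide) are placed at preferred phases equally spaced over an interval of
  width `min(2*pi, nItems * itemPhaseSpacing)` centred on the theta peak,
  each jittered by a wrapped-normal draw with concentration
  `max(couplingBaseKappa - dispersionSlope * nItems, 0.25)`. Both the
  widening span and the shrinking concentration implement "gamma becomes
  more distributed across the cycle with load". The wrapped-normal choice
  gives a closed-form resultant `exp(-sigma^2/2)` used as a test oracle.
* **1/f background.** Exact-slope `1/f^chi` noise produced by sampling the
  white complex spectrum and shaping it by `f^(-chi/2)` (spectral shaping,
  not an autoregressive approximation, so the target slope is exact in
  expectation). Default `chi = 1`, noise SD 1 -- about an order of
  magnitude more background variance than any single narrowband component,
  which keeps single-epoch estimates realistically noisy.
* **Optional confound generators.** `asymmetry` skews the theta waveform by
  a monotone within-cycle time warp so ascending/descending durations have
  ratio `(1+a)/(1-a)` at fixed period; `injectEvoked()` adds an identical
  (phase-locked) Gaussian-windowed theta transient to every epoch.

`generateParticipant()` binds task labels to signals: cue epochs carry the
trial's shortest distance as load; move epochs carry the steps remaining on
the shortest path *from the current cell*, recomputed at every press so the
semantics extend naturally to detours on incorrect trials. The final press
of each trial (goal visible on screen) is labelled for exclusion.

## Default effect sizes

The hypotheses fix only the *directions* of the load effects, not their
magnitudes, so the defaults are a modelling choice made once:
`thetaAmpSlope = 0.15` per step and (`itemPhaseSpacing = pi/3`,
`dispersionSlope = 3`, `gammaAmp = 0.6`). An a priori power check at the
study scale (23 participants x 100 trials) puts the group-level effect
sizes at Cohen's d above 10 for theta power and around -1.3 to -1.8 for
residualized fast-gamma PAC, i.e. recovery power well above 99% -- strong
but within the range such paradigms report, and deliberately not marginal,
since the recovery suite is a correctness check of the chain rather than a
power study.

# The analysis chain

* **Time-frequency power** (`morletTFR()`): five-cycle complex Morlet
  wavelets on a 20-point log-spaced 1-30 Hz grid, power log-transformed
  (natural log -- the base only rescales every downstream contrast), then
  baseline-corrected per frequency and epoch (`baselineCorrect()`): cue
  epochs against -1.5..-0.5 s before cue onset, cropped to the 0-3 s cue
  period; move epochs against -1..-0.5 s before the press, cropped to
  -1..1 s. Samples within half a wavelet of an epoch edge are masked and
  can never enter a baseline or a statistic; epochs are cut long precisely
  so the analysis windows clear these margins, and the code enforces it.
* **Band power** for regressions is deliberately *raw* (never
  baseline-corrected), matching the convention for trial-wise covariates
  and outcomes; it is computed as the mean squared Hilbert envelope over
  the analysis window.
* **PAC** (`pacTable()`, `mvlPac()`): zero-phase FIR band-pass (windowed
  sinc, odd length of three cycles of the band's low edge, applied through
  its exact forward-backward magnitude response), Hilbert analytic signal,
  then the amplitude-weighted mean vector length
  `|sum(a e^{i phi})| / sum(a)` of low-theta phase against gamma amplitude
  (slow 30-70 Hz, fast 70-140 Hz) over the same windows as the power
  analyses. The amplitude-normalized form is primary (bounded,
  dimensionless, exactly invariant to amplitude scaling and phase
  rotation); the unnormalized mean-vector variant is also computed.
* **Power residualization** (`residualizePac()`): per participant, ordinary
  least squares of raw MVL on intercept + theta power + gamma power from
  the same window; the residuals -- orthogonal to both powers by
  construction -- are the coupling outcome entered into distance
  regressions. This is the standard guard against trial-wise power/SNR
  driving apparent coupling changes.
* **Statistics** (`epochRegression()`, `groupTest()`): distance enters as a
  continuous integer regressor (shortest distance for cue epochs, steps
  remaining for move epochs) with trial number as a nuisance regressor
  against slow drift; per-participant coefficients go into two-sided
  one-sample t-tests with Cohen's d = mean/sd. Slices: correct/incorrect,
  and novel/previously-traversed within correct trials. Distance profiles
  (`distanceProfile()`) use categorical bins 3-5 for display only,
  descending during navigation; corner-to-corner distance-6 trials are
  generated (the rule admits them) but excluded from display bins. No
  multiple-testing correction is applied inside the pipeline; the report
  lists every test run so users can correct externally.

# Confound controls

* **Aperiodic slope** (`fitAperiodic()`, `aperiodicVsDistance()`): Welch
  spectra (1 s Hann segments, 50% overlap) averaged per goal distance, then
  an iterative robust line fit in log-log space which excludes points more
  than 3 scaled MADs above the line (oscillatory peaks) and refits until
  stable. Only the slope is used, so no Gaussian peak model is fitted. A
  distance-flat exponent is the desired control outcome.
* **Evoked amplitude** (`evokedAmplitudeByDistance()`): trials subsampled
  to equal counts per distance (distances above 4 dropped -- few long-path
  trials), raw signals averaged within distance, the average
  Morlet-transformed and its theta amplitude extracted; 100 subsampling
  repetitions are averaged. Because induced oscillations have random phase
  they cancel in the average, isolating the phase-locked component.
* **Waveform asymmetry** (`asymmetryIndex()`, `asymmetryVsDistance()`):
  zero-phase Butterworth 2-5 Hz filtering, extrema located by zero-crossing
  bracketing (exactly one peak between an up- and a down-crossing, which
  defeats noise-induced double extrema; edge cycles discarded), per-cycle
  index (ascent - descent)/(ascent + descent), averaged when at least three
  full cycles exist. The index is exactly antisymmetric under time reversal
  and invariant to amplitude scaling and offsets.

  One property worth knowing: waveform skew lives in the *harmonics* of the
  rhythm, and a narrow 2-5 Hz band around a 4 Hz carrier removes them, so
  the filtered index underestimates the physical duty-cycle ratio by an
  order of magnitude. It still tracks *relative* asymmetry across
  conditions, which is all the distance-regression control needs.
  `asymmetryIndex(band = NULL)` skips filtering and recovers the exact
  injected skew on clean signals; the test suite uses that configuration as
  the exact oracle.

# Numerical choices

* Zero-phase filtering is implemented in the frequency domain as
  multiplication by `|H(w)|^2`, the exact forward-backward magnitude
  response; with FFT padding to `n + L` the result equals the exact linear
  convolution at every retained sample. Half a filter length is masked at
  each epoch end and the analysis windows must lie inside the unmasked
  region. The Butterworth family uses its analytic frequency response the
  same way (its ringing decays well inside the masked region; agreement
  with sequential forward-backward IIR filtering away from the edges is
  asserted by test).
* The hot paths -- epoch synthesis and the multi-band analytic transform --
  are compiled (Rcpp/RcppArmadillo) with a single shared forward FFT per
  participant; all randomness flows from R's RNG, so results are
  bit-reproducible under `set.seed()`/`seed` arguments everywhere.
* The three-cycle FIR at a 2 Hz low edge has a ~2 Hz transition band, so
  the squared response is ~0.83 at the 4 Hz carrier: a fixed gain that
  cancels from every contrast and regression the package performs, but
  worth remembering when reading absolute band power.
* Degenerate inputs error loudly rather than silently: all-zero signals for
  the analytic transform, windows overlapping masked edges, fewer than two
  distance levels, zero-variance group tests, collinear designs (the
  residualization GLM drops the gamma covariate with a warning instead,
  since that collinearity is data-dependent).

# What the recovery suite does and does not show

The acceptance-level tests simulate cohorts of 23 participants x 100 trials
(the study scale) and require the group tests to recover the predicted
signs -- theta power rising, residual PAC falling with distance to goal --
in at least 95% of 100 cohorts, while fully null generators (no load
modulation, no bursts) must reject at the nominal 5% rate, and
constant-asymmetry / constant-exponent generators must leave the asymmetry,
1/f-slope and residual-PAC distance regressions null. Cohort counts for the
calibration runs (30 null cohorts at 40 trials each; 20-30 for the
confound controls) and the reduced move-epoch extent (-1.75..1.75 s, the
minimum that keeps the full -1..1 s window clear of the theta filter's
masked edges) are the package's own problem-size choices.

Passing these runs shows the chain is *internally* correct -- estimators
recover what the generator put in, at realistic SNR, and invent nothing
under null conditions. It does not show that real hippocampal data behave
like the generator: real recordings have non-stationary backgrounds,
artifacts, imperfect source reconstruction, heterogeneous carrier
frequencies, and evoked structure, none of which the generator emulates
beyond the specific confounds listed above.

A genuine limitation surfaced by the null experiments: when the *number* of
gamma bursts scales with load but their phases do not disperse, gamma-band
SNR still rises with load and raw MVL rises with it; the linear power GLM
absorbs most but not all of this (the MVL-power relation is nonlinear), so
residualized PAC can retain a small systematic distance dependence in that
regime. The condition-specific tests therefore use burst-free backgrounds
as the no-coupling condition, and users comparing conditions with very
different gamma SNR should treat small residual-PAC effects with care.

# Session info

```{r, eval = FALSE}
sessionInfo()
```
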