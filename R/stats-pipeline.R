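# Trial/epoch-level regressions against goal distance with nuisance
# regressors, group-level inference, and the orchestration that reproduces
# the full analysis logic on any EpochSet.

#' Default analysis configuration
#'
#' The analysis constants: theta bands 2--5 and 6--9 Hz; gamma bands 30--70
#' (slow) and 70--140 Hz (fast); 0--3 s cue window; \[-1, 1\] s window
#' around each button press; display bins at distances 3--5; final-step and
#' simultaneous-press exclusions on; distance treated as a continuous
#' integer regressor with trial number as nuisance; two-sided alpha 0.05.
#'
#' @param ... named overrides of any default.
#' @return a named list.
#' @export
analysisConfig <- function(...) {
  cfg <- list(
    thetaBands = list(theta_low = c(2, 5), theta_high = c(6, 9)),
    gammaBands = list(slow = c(30, 70), fast = c(70, 140)),
    cueWindow = c(0, 3),
    moveWindow = c(-1, 1),
    bins = 3:5,
    excludeFinalStep = TRUE,
    excludeDistance6Bins = TRUE,
    alpha = 0.05,
    firCycles = 3,
    mvlNormalize = TRUE,
    outcomes = c("theta_low", "theta_high", "pac_fast", "pac_slow"),
    slices = c("correct", "incorrect", "novel", "traversed"))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Epoch-level regression of an outcome on goal distance
#'
#' Ordinary least squares of a per-epoch outcome on distance (integer
#' steps, continuous) plus trial number as a nuisance regressor. Distance
#' is the shortest start-to-goal distance for cue epochs and the steps
#' remaining for move epochs; the caller passes the appropriate label.
#'
#' @param outcome numeric per-epoch outcome (band power, residual PAC,
#'   asymmetry index, ...).
#' @param distance integer per-epoch distance.
#' @param trialNumber optional nuisance regressor; NULL omits it.
#' @return list of class `RegressionResult`: `beta_distance`, `beta_trial`
#'   (NA when omitted), `intercept`, `n`.
#' @export
epochRegression <- function(outcome, distance, trialNumber = NULL) {
  ok <- stats::complete.cases(outcome, distance,
                              if (is.null(trialNumber)) rep(0, length(outcome))
                              else trialNumber)
  outcome <- outcome[ok]; distance <- distance[ok]
  if (!is.null(trialNumber)) trialNumber <- trialNumber[ok]
  if (length(unique(distance)) < 2L)
    stop("fewer than 2 distance levels in this slice")
  X <- if (is.null(trialNumber)) cbind(intercept = 1, distance = distance)
       else cbind(intercept = 1, distance = distance, trial = trialNumber)
  if (nrow(X) < ncol(X) + 2L) stop("too few epochs for the regression")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("collinear design; offending column(s): ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, outcome)
  structure(list(beta_distance = unname(beta["distance"]),
                 beta_trial = if ("trial" %in% names(beta))
                   unname(beta["trial"]) else NA_real_,
                 intercept = unname(beta["intercept"]),
                 n = length(outcome)),
            class = "RegressionResult")
}

#' Group-level t-test on per-participant regression coefficients
#'
#' Two-sided one-sample t-test of the betas against zero (or paired t-test
#' on the difference of two matched vectors), with Cohen's d computed as
#' mean/sd (one-sample) or mean(diff)/sd(diff) (paired).
#'
#' @param betas numeric per-participant coefficients.
#' @param betas2 matched second vector for `mode = "paired"`.
#' @param mode "one_sample" or "paired".
#' @return one-row data.frame: `test`, `t`, `df`, `p`, `cohens_d`, `n`.
#' @export
groupTest <- function(betas, betas2 = NULL, mode = c("one_sample", "paired")) {
  mode <- match.arg(mode)
  x <- if (mode == "paired") {
    stopifnot(!is.null(betas2), length(betas) == length(betas2))
    betas - betas2
  } else betas
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 participants")
  if (stats::sd(x) == 0) stop("zero variance across participants: t undefined")
  tt <- stats::t.test(x, mu = 0, alternative = "two.sided")
  data.frame(test = mode, t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             cohens_d = mean(x) / stats::sd(x), n = n)
}

#' Per-distance outcome profile
#'
#' Mean and dispersion of an outcome per distance bin (categorical bins are
#' used for display only; inference uses the continuous regression).
#' Navigation profiles are conventionally ordered by descending distance,
#' mirroring the approach to the goal. Empty bins are reported as NA rows,
#' never dropped silently.
#'
#' @param outcome numeric per-epoch outcome.
#' @param distance integer per-epoch distance.
#' @param bins distance bins to report.
#' @param descending order bins by descending distance.
#' @return data.frame: `distance`, `mean`, `sd`, `n`.
#' @export
distanceProfile <- function(outcome, distance, bins = 3:5, descending = TRUE) {
  stopifnot(length(bins) > 0L)
  if (descending) bins <- sort(bins, decreasing = TRUE)
  rows <- lapply(bins, function(b) {
    v <- outcome[distance == b]
    data.frame(distance = b,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v))
  })
  do.call(rbind, rows)
}

# Epoch index sets for the standard slices. Novel/traversed are defined on
# correct trials, so correct = novel + traversed and
# correct + incorrect = all retained.
.sliceIndex <- function(lab, slice) {
  switch(slice,
    correct = which(lab$correct),
    incorrect = which(!lab$correct),
    novel = which(lab$correct & lab$novel),
    traversed = which(lab$correct & !lab$novel),
    stop("unknown slice: ", slice))
}

# Per-epoch outcomes for one participant's move (or cue) EpochSet: raw
# band powers for the requested theta bands and residualized PAC for the
# requested gamma bands. The narrowband transforms run in the compiled
# kernel with one shared forward FFT; the phase band (low theta, the widest
# filter) must come first in the band list so its analytic signal is
# available when the amplitude bands are processed, and its edge mask
# defines the PAC window.
.participantOutcomes <- function(epochs, window, config) {
  x <- signalMatrix(epochs)
  fs <- sampleRate(epochs)
  tm <- epochTimes(epochs)
  out <- epochLabels(epochs)
  want <- config$outcomes
  needPac <- any(grepl("^pac_", want))
  bands <- list()
  if (needPac) bands$theta_low <- config$thetaBands$theta_low
  for (nm in names(config$thetaBands))
    if (nm %in% want && is.null(bands[[nm]]))
      bands[[nm]] <- config$thetaBands[[nm]]
  for (gb in names(config$gammaBands))
    if (paste0("pac_", gb) %in% want)
      bands[[paste0("gamma_", gb)]] <- config$gammaBands[[gb]]
  taps <- lapply(bands, .firBandpass, sampleRate = fs,
                 cycles = config$firCycles)
  nfft <- nextFastLen(nrow(x) + max(lengths(taps)))
  wIdx <- windowIndex(tm, window)
  phaseBand <- if (needPac) match("theta_low", names(bands)) else 0L
  res <- cppBandOutcomes(x, taps, phaseBand, wIdx,
                         isTRUE(config$mvlNormalize), nfft)
  if (needPac && res$n_phase_samples < 5 * fs / mean(bands$theta_low))
    stop("analysis window too short: need >= 5 cycles of the phase band ",
         "outside the filter edges")
  for (i in seq_along(bands)) {
    nm <- names(bands)[i]
    if (nm %in% want) out[[nm]] <- as.numeric(res$power[[i]])
  }
  if (needPac) {
    thetaPow <- as.numeric(res$power_phase_idx[[phaseBand]])
    for (gb in names(config$gammaBands)) {
      oc <- paste0("pac_", gb)
      if (!oc %in% want) next
      i <- match(paste0("gamma_", gb), names(bands))
      mvl <- as.numeric(res$mvl[[i]])
      tbl <- data.frame(raw_mvl = mvl, theta_power = thetaPow,
                        gamma_power = as.numeric(res$power_phase_idx[[i]]))
      out[[oc]] <- residualizePac(tbl)$residual_pac
      out[[paste0("raw_mvl_", gb)]] <- mvl
    }
  }
  out
}

#' Per-participant navigation statistics
#'
#' Computes, for one participant's move epochs, the per-epoch outcomes
#' (theta band powers, residualized PAC per gamma band) and the slice-wise
#' regressions against steps remaining with trial number as nuisance.
#' Final-step epochs (goal visible on screen) are excluded when configured.
#'
#' @param epochs the participant's move [EpochSet-class].
#' @param config an [analysisConfig()] list.
#' @return list: `betas` (data.frame outcome x slice with `beta_distance`,
#'   `n`), `outcomes` (the per-epoch outcome table after exclusions).
#' @export
participantNavigationStats <- function(epochs, config = analysisConfig()) {
  stopifnot(is(epochs, "EpochSet"))
  lab <- epochLabels(epochs)
  keep <- rep(TRUE, nrow(lab))
  if (isTRUE(config$excludeFinalStep) && "final_step" %in% names(lab))
    keep <- keep & !lab$final_step
  epochs <- epochs[, keep]
  tab <- .participantOutcomes(epochs, config$moveWindow, config)
  rows <- list()
  for (oc in config$outcomes) {
    for (sl in config$slices) {
      idx <- .sliceIndex(tab, sl)
      if (length(idx) < 5L || length(unique(tab$steps_remaining[idx])) < 2L)
        next
      rr <- epochRegression(tab[[oc]][idx], tab$steps_remaining[idx],
                            tab$trial_number[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, slice = sl, beta_distance = rr$beta_distance,
        beta_trial = rr$beta_trial, n = rr$n)
    }
  }
  list(betas = do.call(rbind, rows), outcomes = tab)
}

#' Per-participant planning (cue-period) statistics
#'
#' Low-theta (2--5 Hz) power over the 0--3 s cue window, raw (not
#' baseline-corrected, matching the regression convention), regressed on
#' the shortest start-to-goal distance per slice with trial number as
#' nuisance.
#'
#' @param epochs the participant's cue [EpochSet-class].
#' @param config an [analysisConfig()] list.
#' @return as [participantNavigationStats()].
#' @export
participantCueStats <- function(epochs, config = analysisConfig()) {
  stopifnot(is(epochs, "EpochSet"))
  cfgCue <- config
  cfgCue$outcomes <- intersect(config$outcomes, c("theta_low", "theta_high"))
  tab <- .participantOutcomes(epochs, config$cueWindow, cfgCue)
  rows <- list()
  for (oc in cfgCue$outcomes) {
    for (sl in config$slices) {
      idx <- .sliceIndex(tab, sl)
      if (length(idx) < 5L || length(unique(tab$goal_distance[idx])) < 2L)
        next
      rr <- epochRegression(tab[[oc]][idx], tab$goal_distance[idx],
                            tab$trial_number[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, slice = sl, beta_distance = rr$beta_distance,
        beta_trial = rr$beta_trial, n = rr$n)
    }
  }
  list(betas = do.call(rbind, rows), outcomes = tab)
}

# Shared group-level assembly: stack per-participant beta tables, run the
# one-sample t-test per outcome x slice, and build distance profiles.
.groupReport <- function(perParticipant, config, distanceCol) {
  betas <- do.call(rbind, lapply(seq_along(perParticipant), function(i) {
    b <- perParticipant[[i]]$betas
    if (is.null(b)) return(NULL)
    b$participant <- i
    b
  }))
  combos <- unique(betas[, c("outcome", "slice")])
  group <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    sel <- betas$outcome == combos$outcome[k] & betas$slice == combos$slice[k]
    gt <- groupTest(betas$beta_distance[sel])
    cbind(combos[k, , drop = FALSE], gt, row.names = NULL)
  }))
  bins <- config$bins
  profiles <- lapply(stats::setNames(nm = unique(betas$outcome)), function(oc) {
    per <- lapply(perParticipant, function(p) {
      tab <- p$outcomes
      idx <- .sliceIndex(tab, "correct")
      distanceProfile(tab[[oc]][idx], tab[[distanceCol]][idx], bins = bins)
    })
    agg <- do.call(rbind, per)
    stats::aggregate(cbind(mean, n) ~ distance, data = agg, FUN = mean,
                     na.action = stats::na.omit)
  })
  list(betas = betas, group = group, profiles = profiles, config = config)
}

#' Group-level navigation analysis
#'
#' Runs [participantNavigationStats()] for every participant and submits
#' the per-participant distance coefficients to one-sample t-tests per
#' outcome and slice; also returns group distance profiles (descending
#' bins). Under the sequence-coding model theta-band power slopes are
#' positive and residual-PAC slopes negative.
#'
#' @param participants list of move [EpochSet-class] objects, one per
#'   participant.
#' @param config an [analysisConfig()] list.
#' @return list of class `ResultsReport`: `betas`, `group`, `profiles`,
#'   `config`.
#' @export
runNavigationAnalysis <- function(participants, config = analysisConfig()) {
  per <- lapply(participants, participantNavigationStats, config = config)
  out <- .groupReport(per, config, "steps_remaining")
  class(out) <- "ResultsReport"
  out
}

#' Group-level planning (cue) analysis
#'
#' @param participants list of cue [EpochSet-class] objects.
#' @param config an [analysisConfig()] list.
#' @return list of class `ResultsReport`.
#' @export
runCueAnalysis <- function(participants, config = analysisConfig()) {
  per <- lapply(participants, participantCueStats, config = config)
  out <- .groupReport(per, config, "goal_distance")
  class(out) <- "ResultsReport"
  out
}

#' Simulate and analyse a full synthetic cohort
#'
#' Generates `nParticipants` sessions and signal sets under the given
#' generator parameters, runs the navigation pipeline per participant, and
#' returns the per-participant betas plus group tests. Participants are
#' processed one at a time so memory stays flat; per-participant seeds are
#' derived reproducibly from `seed`.
#'
#' @param nParticipants,nTrials cohort size (study conditions: 23
#'   participants, 100 trials).
#' @param params a [SignalParams-class] for the generator.
#' @param pCorrect agent accuracy.
#' @param seed master seed.
#' @param epochWindow move-epoch extent (s) around each press; the default
#'   \[-1.75, 1.75\] leaves the full \[-1, 1\] analysis window outside the
#'   theta filter's masked edges.
#' @param config an [analysisConfig()] list.
#' @param paramsNovel optional novel-trial parameter set (condition-specific
#'   effects).
#' @return list: `betas` (stacked per-participant), `group` (per
#'   outcome x slice).
#' @export
runCohort <- function(nParticipants = 23, nTrials = 100,
                      params = signalParams(), pCorrect = 0.85, seed = NULL,
                      epochWindow = c(-1.75, 1.75),
                      config = analysisConfig(), paramsNovel = NULL,
                      paramsIncorrect = NULL) {
  seeds <- subSeeds(seed, 2L * nParticipants)
  per <- vector("list", nParticipants)
  for (i in seq_len(nParticipants)) {
    ses <- simulateAgent(generateSession(nTrials = nTrials,
                                         seed = seeds[2L * i - 1L]),
                         pCorrect = pCorrect, seed = seeds[2L * i - 1L])
    es <- generateParticipant(params, ses, events = "move",
                              moveWindow = epochWindow, seed = seeds[2L * i],
                              paramsNovel = paramsNovel,
                              paramsIncorrect = paramsIncorrect)
    per[[i]] <- participantNavigationStats(es, config)
  }
  out <- .groupReport(per, config, "steps_remaining")
  out[c("betas", "group")]
}
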