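# Plain-text serialization of EpochSet objects: a CSV holding the
# time-by-epochs signal matrix, a CSV of per-epoch labels, and a JSON
# sidecar with the sampling metadata.

#' Read and write EpochSet objects as text files
#'
#' `writeEpochSet(x, prefix)` writes `<prefix>_signal.csv` (time samples in
#' rows, epochs in columns), `<prefix>_labels.csv` (one row per epoch) and
#' `<prefix>_meta.json` (sample rate and epoch start time).
#' `readEpochSet(prefix)` reconstructs the object.
#'
#' @param x an [EpochSet-class].
#' @param prefix file path prefix.
#' @return `readEpochSet` returns an [EpochSet-class]; `writeEpochSet`
#'   returns `prefix` invisibly.
#' @export
writeEpochSet <- function(x, prefix) {
  stopifnot(is(x, "EpochSet"))
  utils::write.csv(as.data.frame(signalMatrix(x)),
                   paste0(prefix, "_signal.csv"), row.names = FALSE)
  utils::write.csv(epochLabels(x), paste0(prefix, "_labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(sample_rate = sampleRate(x), t_start = epochTimes(x)[1],
         n_samples = nrow(x), n_epochs = ncol(x)),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  sig <- as.matrix(utils::read.csv(paste0(prefix, "_signal.csv")))
  labels <- utils::read.csv(paste0(prefix, "_labels.csv"))
  EpochSet(unname(sig), sampleRate = as.numeric(meta$sample_rate),
           labels = labels, tStart = as.numeric(meta$t_start))
}
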