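#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window, leaving the window mean at zero (to numerical precision) and all
#' other structure untouched. The default window is the 300 ms of fixation
#' preceding idiom-initial onset (-1,400 to -1,100 ms); the same baseline is
#' used for pre- and post-idiom-final analyses (no re-baselining at 0 ms).
#' Window membership is closed on both ends. The operation is idempotent.
#'
#' @param epochs an [epoch_set()].
#' @param window baseline window c(lo, hi) in ms.
#' @return the corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window = c(-1400, -1100)) {
  idx <- window_index(epochs$time, window, "baseline window")
  base <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2L)
  epochs$data <- epochs$data - as.vector(base) # recycles over samples
  epochs$log <- c(epochs$log,
                  sprintf("baseline corrected over [%g, %g] ms",
                          window[1], window[2]))
  epochs
}

#' Reject trials by peak amplitude
#'
#' Removes every trial in which any sample on any channel exceeds the
#' threshold in absolute value (default +/-120 microvolts). Remaining
#' trials keep their order; the rejection rate is logged and the rejected
#' trial indices (positions in the incoming trial table) are returned.
#'
#' @param epochs an [epoch_set()].
#' @param threshold positive amplitude bound in microvolts.
#' @return list with \code{epochs} (survivors) and \code{rejected} (integer
#'   indices of removed trials).
#' @export
reject_amplitude <- function(epochs, threshold = 120) {
  if (!is.numeric(threshold) || threshold <= 0)
    abort("ConfigError", "'threshold' must be positive")
  peak <- apply(abs(epochs$data), 1L, max)
  bad <- which(peak > threshold)
  if (length(bad) == dim(epochs$data)[1])
    abort("AllRejectedError", "every trial exceeds the amplitude threshold")
  if (length(bad)) {
    epochs$data <- epochs$data[-bad, , , drop = FALSE]
    epochs$trials <- epochs$trials[-bad, , drop = FALSE]
    rownames(epochs$trials) <- NULL
  }
  epochs$log <- c(epochs$log,
                  sprintf("rejected %d/%d trials (%.2f%%) at +/-%g uV",
                          length(bad), length(peak),
                          100 * length(bad) / length(peak), threshold))
  list(epochs = epochs, rejected = bad)
}

#' Write a rejection report
#'
#' @param rejection a [reject_amplitude()] result.
#' @param epochs_before the [epoch_set()] the rejection ran on.
#' @param threshold the threshold used.
#' @param path JSON output path.
#' @return the path, invisibly.
#' @export
write_rejection_report <- function(rejection, epochs_before, threshold, path) {
  n <- nrow(epochs_before$trials)
  jsonlite::write_json(list(
    threshold = threshold,
    n_trials = n,
    rejected_index = rejection$rejected,
    rejected_trials = epochs_before$trials[rejection$rejected, , drop = FALSE],
    rate = length(rejection$rejected) / n
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
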