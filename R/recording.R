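#' Construct an ECoG recording object
#'
#' A thin container for a channels x samples signal matrix (microvolts)
#' with its sampling rate and a channel table giving grid membership and a
#' coarse region label per channel.
#'
#' @param signals numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channels data.frame with at least columns `channel` (unique ids),
#'   `grid` (grid/strip id used for common-average referencing) and
#'   `region` (free label, e.g. "motor", "temporal", "other").
#' @return an object of class `ecog_recording`.
#' @export
ecog_recording <- function(signals, fs, channels) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  stopifnot(is.numeric(signals), fs > 0)
  if (!is.data.frame(channels) ||
      !all(c("channel", "grid") %in% names(channels))) {
    stop("ecog_recording: channel table must have columns 'channel' and 'grid'")
  }
  if (nrow(channels) != nrow(signals)) {
    stop(sprintf(
      "ecog_recording: %d channel rows for %d signal rows",
      nrow(channels), nrow(signals)
    ))
  }
  if (anyNA(channels$grid)) {
    stop("ecog_vad: channels without grid assignment are not allowed")
  }
  if (is.null(channels$region)) channels$region <- rep("other", nrow(channels))
  rownames(signals) <- channels$channel
  structure(
    list(signals = signals, fs = fs, channels = channels),
    class = "ecog_recording"
  )
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf(
    "<ecog_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), %d grid(s)\n",
    nrow(x$signals), ncol(x$signals), x$fs, ncol(x$signals) / x$fs,
    length(unique(x$channels$grid))
  ))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param rec an `ecog_recording`.
#' @return `n_samples`: integer; `duration`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$signals)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$signals) / rec$fs
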