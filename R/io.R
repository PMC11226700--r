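# Readers and writers. Recordings use a plain-text container (a TSV signal
# matrix plus a JSON metadata sidecar); events follow the BIDS-iEEG TSV
# convention (onset + duration in seconds, 0-based from recording start).

#' Write a recording to the text container format
#'
#' Produces `<path>.signals.tsv` (samples in rows, one column per channel,
#' full double precision) and `<path>.meta.json` (sampling rate and channel
#' table). The round trip through [read_recording()] is lossless.
#'
#' @param rec an `ecog_recording`.
#' @param path file path prefix (no extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  sig <- t(rec$signals)
  con <- file(paste0(path, ".signals.tsv"), "w")
  writeLines(paste(rec$channels$channel, collapse = "\t"), con)
  body <- apply(sig, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  close(con)
  jsonlite::write_json(
    list(fs = rec$fs, channels = rec$channels),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a recording from the text container format
#'
#' @param path file path prefix used with [write_recording()].
#' @return an `ecog_recording`.
#' @export
read_recording <- function(path) {
  meta_file <- paste0(path, ".meta.json")
  sig_file <- paste0(path, ".signals.tsv")
  if (!file.exists(meta_file)) {
    stop("read_recording: missing channel table / metadata file ", meta_file)
  }
  if (!file.exists(sig_file)) stop("read_recording: missing ", sig_file)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (is.null(meta$channels) || is.null(meta$fs)) {
    stop("read_recording: metadata lacks 'fs' or 'channels'")
  }
  sig <- utils::read.table(sig_file, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "numeric")
  ecog_recording(t(as.matrix(sig)), meta$fs, as.data.frame(meta$channels))
}

#' Write an events table in BIDS-iEEG flavor
#'
#' One row per event with columns `onset`, `duration`, `trial`, `mode`,
#' `event_type` (`task_cue`, `go_cue`, `speech`). Imagined trials emit no
#' `speech` events — their timing is not observable.
#'
#' @param trials observable trial table from [make_paradigm()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(trials, path) {
  ev <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    ev[[length(ev) + 1]] <- data.frame(
      onset = tr$cue_onset, duration = tr$go_onset - tr$cue_onset,
      trial = tr$trial, mode = tr$mode, event_type = "task_cue"
    )
    ev[[length(ev) + 1]] <- data.frame(
      onset = tr$go_onset, duration = 0,
      trial = tr$trial, mode = tr$mode, event_type = "go_cue"
    )
    if (!is.na(tr$speech_onset)) {
      ev[[length(ev) + 1]] <- data.frame(
        onset = tr$speech_onset, duration = tr$speech_offset - tr$speech_onset,
        trial = tr$trial, mode = tr$mode, event_type = "speech"
      )
    }
  }
  out <- do.call(rbind, ev)
  utils::write.table(format(out, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-flavor events TSV
#' @param path TSV path written by [write_events_tsv()].
#' @return data.frame of events.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write the hidden ground truth (never read by the pipeline)
#'
#' @param ground_truth ground-truth table from [make_paradigm()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_tsv <- function(ground_truth, path) {
  utils::write.table(format(ground_truth, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a frame dataset as TSV
#'
#' One row per frame: `trial`, `time`, `label` (empty for unlabeled) and
#' the feature columns. Band subset and frame rate ride along in a `#`
#' header comment.
#'
#' @param frames a `frame_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_frames_tsv <- function(frames, path) {
  con <- file(path, "w")
  writeLines(sprintf("# ecogvad frames fs=%.10g band_subset=%s",
                     frames$fs, frames$band_subset), con)
  df <- data.frame(trial = frames$trial, time = frames$time,
                   label = frames$label, check.names = FALSE)
  df <- cbind(df, as.data.frame(frames$X, check.names = FALSE))
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a frame dataset written by [write_frames_tsv()]
#' @param path TSV path.
#' @return a `frame_dataset`.
#' @export
read_frames_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", hdr))
  bs <- sub(".*band_subset=(\\S+).*", "\\1", hdr)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          check.names = FALSE)
  X <- as.matrix(df[, -(1:3), drop = FALSE])
  frame_dataset(X, df$trial, df$time, df$label, fs = fs, band_subset = bs)
}
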