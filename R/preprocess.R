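# Preprocessing: artifact screening, per-grid common-average referencing,
# line-noise removal, the 7-band envelope extraction, and the 21-dimensional
# lagged frame features.

#' Screen channels for amplitude artifacts
#'
#' A channel is rejected if its absolute amplitude exceeds `limit` anywhere
#' in the recording; rejected channels are excluded from every later stage,
#' including the common-average reference.
#'
#' @param rec an `ecog_recording`.
#' @param limit voltage limit in microvolts (default 1000, i.e. 1 mV).
#' @return logical vector, `TRUE` for retained channels.
#' @export
screen_artifacts <- function(rec, limit = 1000) {
  stopifnot(limit > 0)
  if (n_samples(rec) == 0 || nrow(rec$signals) == 0) {
    return(logical(nrow(rec$signals)))
  }
  apply(rec$signals, 1, function(x) max(abs(x)) <= limit)
}

#' Drop channels from a recording
#' @param rec an `ecog_recording`.
#' @param keep logical or index vector of channels to retain.
#' @return an `ecog_recording` with the remaining channels.
#' @export
subset_channels <- function(rec, keep) {
  ecog_recording(rec$signals[keep, , drop = FALSE], rec$fs,
                 rec$channels[keep, , drop = FALSE])
}

#' Common-average reference per grid
#'
#' Subtracts, at every sample, the mean over the retained channels of each
#' grid from each of that grid's channels. After referencing, the
#' within-grid channel mean is zero everywhere; a single-channel grid
#' becomes identically zero.
#'
#' @param rec an `ecog_recording` (already artifact-screened).
#' @return re-referenced `ecog_recording`.
#' @export
common_average_reference <- function(rec) {
  grids <- unique(rec$channels$grid)
  sig <- rec$signals
  for (g in grids) {
    idx <- which(rec$channels$grid == g)
    if (length(idx) == 0) stop("common_average_reference: grid with no retained channels")
    avg <- colMeans(sig[idx, , drop = FALSE])
    sig[idx, ] <- sweep(sig[idx, , drop = FALSE], 2, avg)
  }
  ecog_recording(sig, rec$fs, rec$channels)
}

#' Remove power-line noise with a zero-phase notch
#'
#' 4th-order zero-phase Butterworth band-stop filters of width +/-2 Hz at
#' the line frequency and its first harmonic (the harmonic is skipped if at
#' or above Nyquist).
#'
#' @param rec an `ecog_recording`.
#' @param line_freq line frequency in Hz (default 50).
#' @return filtered `ecog_recording`.
#' @export
notch_line_noise <- function(rec, line_freq = 50) {
  if (line_freq >= rec$fs / 2) stop("notch_line_noise: line frequency above Nyquist")
  freqs <- line_freq * c(1, 2)
  freqs <- freqs[freqs < rec$fs / 2 - 2]
  sig <- rec$signals
  for (f in freqs) {
    filt <- butter_sos(4, c(f - 2, f + 2), rec$fs, "stop")
    for (ch in seq_len(nrow(sig))) {
      sig[ch, ] <- filtfilt_sos(filt, sig[ch, ], pad = min(ncol(sig) - 1, 3 * rec$fs))
    }
  }
  ecog_recording(sig, rec$fs, rec$channels)
}

#' Extract smoothed Hilbert envelopes in the seven canonical bands
#'
#' Per channel and band: 4th-order Butterworth band-pass applied
#' forward-backward (zero phase), analytic-signal magnitude, then a
#' 4th-order zero-phase Butterworth low-pass at `smooth_hz` (default
#' 0.25 Hz). The single heavy smoother replaces the usual stack of
#' envelope smoothing, output smoothing and debouncing.
#'
#' @param rec an `ecog_recording`.
#' @param bands a `band_set` (defaults to the canonical seven bands).
#' @param smooth_hz envelope low-pass cutoff in Hz.
#' @return list of class `envelope_tensor`: `values` (channels x bands x
#'   samples array), `fs`, `bands`, `channels`.
#' @export
extract_envelopes <- function(rec, bands = band_set(rec$fs), smooth_hz = 0.25) {
  if (any(bands$high >= rec$fs / 2)) {
    stop("extract_envelopes: band edge at or above Nyquist")
  }
  n <- n_samples(rec)
  if (n / rec$fs < 20) {
    warning("extract_envelopes: recording shorter than 20 s; envelope edges will be unreliable")
  }
  lp <- butter_sos(4, smooth_hz, rec$fs, "low")
  lp_pad <- min(n - 1, ceiling(3 * rec$fs / smooth_hz))
  nc <- nrow(rec$signals)
  vals <- array(0, dim = c(nc, nrow(bands), n))
  for (b in seq_len(nrow(bands))) {
    bp <- butter_sos(4, c(bands$low[b], bands$high[b]), rec$fs, "pass")
    bp_pad <- min(n - 1, ceiling(3 * rec$fs / bands$low[b]))
    for (ch in seq_len(nc)) {
      y <- filtfilt_sos(bp, rec$signals[ch, ], pad = bp_pad)
      env <- hilbert_envelope(y)
      vals[ch, b, ] <- filtfilt_sos(lp, env, pad = lp_pad)
    }
  }
  structure(
    list(values = vals, fs = rec$fs, bands = bands, channels = rec$channels),
    class = "envelope_tensor"
  )
}

#' @export
print.envelope_tensor <- function(x, ...) {
  cat(sprintf("<envelope_tensor> %d channel(s) x %d bands x %d samples @ %g Hz\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$fs))
  invisible(x)
}

#' Frame times covering each trial
#'
#' Generates evenly spaced frame times inside every trial span, with the
#' trial id attached. `stride` subsamples the native envelope rate for
#' speed (1 = one frame per sample).
#'
#' @param trials observable trial table from [make_paradigm()] (or any
#'   data.frame with trial, trial_start, trial_end).
#' @param fs sampling rate in Hz.
#' @param stride frame stride in samples.
#' @return data.frame with columns `trial`, `time`.
#' @export
trial_frames <- function(trials, fs, stride = 1) {
  out <- lapply(seq_len(nrow(trials)), function(i) {
    tt <- seq(trials$trial_start[i], trials$trial_end[i] - 1 / fs, by = stride / fs)
    data.frame(trial = trials$trial[i], time = tt)
  })
  do.call(rbind, out)
}

#' Build lagged envelope features for one channel
#'
#' For each frame time the feature vector holds each band's smoothed
#' envelope at the frame time and at -125 ms and +125 ms (lag offset =
#' `round(0.125 * fs)` samples). Column order is band-major, lag-minor:
#' `delta.m125, delta.c0, delta.p125, theta.m125, ...`. Frames closer than
#' 125 ms to either record edge are dropped (a message reports the count).
#'
#' @param env an `envelope_tensor`.
#' @param channel channel id or index.
#' @param frames data.frame with columns `time` (s) and optionally `trial`.
#' @param band_subset `"full"` (21 features), `"low"` (15) or `"gamma"` (6).
#' @return a `frame_dataset`: list with `X` (feature matrix), `trial`,
#'   `time`, `label` (initialized to `NA`, meaning unlabeled), `fs`,
#'   `band_subset`.
#' @export
build_features <- function(env, channel, frames,
                           band_subset = c("full", "low", "gamma")) {
  band_subset <- match.arg(band_subset)
  if (is.character(channel)) {
    channel <- match(channel, env$channels$channel)
    if (is.na(channel)) stop("build_features: unknown channel id")
  }
  n <- dim(env$values)[3]
  lag <- round(0.125 * env$fs)
  idx <- round(frames$time * env$fs) + 1L
  ok <- idx - lag >= 1 & idx + lag <= n
  if (any(!ok)) {
    message(sprintf("build_features: dropped %d frame(s) within 125 ms of a record edge",
                    sum(!ok)))
  }
  idx <- idx[ok]
  keep_bands <- match(band_subset_names(band_subset), env$bands$band)
  X <- matrix(0, nrow = length(idx), ncol = 3 * length(keep_bands))
  col <- 0
  for (b in keep_bands) {
    e <- env$values[channel, b, ]
    for (off in c(-lag, 0L, lag)) {
      col <- col + 1
      X[, col] <- e[idx + off]
    }
  }
  colnames(X) <- feature_colnames(env$bands$band[keep_bands])
  frame_dataset(
    X = X,
    trial = if (!is.null(frames$trial)) frames$trial[ok] else rep(NA_integer_, length(idx)),
    time = frames$time[ok],
    label = rep(NA_real_, length(idx)),
    fs = env$fs, band_subset = band_subset
  )
}

#' Construct a frame dataset
#'
#' The per-frame container used by the detector: a feature matrix plus the
#' trial id, time and label (+1 speech, -1 silence, `NA` unlabeled) of
#' every row.
#'
#' @param X numeric feature matrix (frames x features).
#' @param trial,time,label per-frame vectors matching `nrow(X)`.
#' @param fs sampling rate the frames were taken at.
#' @param band_subset tag recording which bands `X` holds.
#' @return list of class `frame_dataset`.
#' @export
frame_dataset <- function(X, trial, time, label = rep(NA_real_, nrow(X)),
                          fs = 256, band_subset = "full") {
  X <- as.matrix(X)
  stopifnot(length(trial) == nrow(X), length(time) == nrow(X),
            length(label) == nrow(X))
  structure(
    list(X = X, trial = trial, time = time, label = as.numeric(label),
         fs = fs, band_subset = band_subset),
    class = "frame_dataset"
  )
}

#' @export
print.frame_dataset <- function(x, ...) {
  lab <- table(factor(x$label, levels = c(-1, 1)), useNA = "always")
  cat(sprintf(
    "<frame_dataset> %d frames x %d features (%s bands), %d trial(s); labels -1/+1/NA: %d/%d/%d\n",
    nrow(x$X), ncol(x$X), x$band_subset, length(unique(x$trial)),
    lab[1], lab[2], lab[3]
  ))
  invisible(x)
}

#' Subset the rows of a frame dataset
#' @param frames a `frame_dataset`.
#' @param i row index (logical or integer).
#' @return a `frame_dataset` with the selected rows.
#' @export
subset_frames <- function(frames, i) {
  frame_dataset(frames$X[i, , drop = FALSE], frames$trial[i], frames$time[i],
                frames$label[i], frames$fs, frames$band_subset)
}

#' Z-score features with training-set statistics
#'
#' Column means and standard deviations are estimated on `train` only and
#' applied to `apply_to` (defaults to `train` itself). Constant training
#' columns are centered and left at zero rather than divided by zero.
#'
#' @param train `frame_dataset` providing the statistics.
#' @param apply_to `frame_dataset` to transform.
#' @return `apply_to` with standardized features; the statistics are
#'   attached as attributes `center` and `scale` on the feature matrix.
#' @export
zscore_features <- function(train, apply_to = train) {
  mu <- colMeans(train$X)
  sdv <- apply(train$X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- Inf # constant column -> zeros
  Xz <- sweep(sweep(apply_to$X, 2, mu), 2, sdv, "/")
  out <- apply_to
  out$X <- Xz
  attr(out$X, "center") <- mu
  attr(out$X, "scale") <- ifelse(is.finite(sdv), sdv, 0)
  out
}
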