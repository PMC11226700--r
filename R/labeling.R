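# Labeling: frame labels from speech windows, per-trial class balancing,
# consensus surrogate timing for imagined trials, and the cue-centered
# passive dataset used as an exclusion criterion.

#' Label frames from per-trial speech windows
#'
#' A frame is labeled +1 (speech) iff its time lies inside its trial's
#' window `[onset, offset]` (boundaries inclusive), else -1.
#'
#' @param frames a `frame_dataset` with trial ids.
#' @param windows data.frame with columns `trial`, `onset`, `offset`
#'   (seconds, same clock as the frame times). Only observable windows —
#'   for imagined trials use the surrogate path
#'   ([surrogate_imagined_timing()]) instead.
#' @return `frames` with `label` filled in.
#' @export
frames_to_labels <- function(frames, windows) {
  if (any(windows$onset >= windows$offset)) {
    stop("frames_to_labels: every window needs onset < offset")
  }
  miss <- setdiff(unique(frames$trial), windows$trial)
  if (length(miss)) {
    stop(sprintf(
      paste0("frames_to_labels: no speech window for trial(s) %s; ",
             "imagined trials have no observable timing - use ",
             "surrogate_imagined_timing()"),
      paste(miss, collapse = ", ")
    ))
  }
  on <- windows$onset[match(frames$trial, windows$trial)]
  off <- windows$offset[match(frames$trial, windows$trial)]
  frames$label <- ifelse(frames$time >= on & frames$time <= off, 1, -1)
  frames
}

#' Select a class-balanced subset of one trial's frames
#'
#' Keeps every speech frame and an equal number of silence frames drawn
#' contiguously around the speech window: split as evenly as possible
#' before and after it, taking the frames nearest the window. If the
#' silence available after the window (before the next trial starts) is
#' short by `k` frames, `k` extra frames are taken before the window
#' instead. Odd counts place the extra frame before the window.
#'
#' @param frames labeled `frame_dataset`.
#' @param trial trial id to balance.
#' @param next_trial_start first time instant that belongs to the next
#'   trial (`Inf` for the last trial).
#' @return integer vector of selected row indices into `frames`.
#' @export
balance_trial <- function(frames, trial, next_trial_start = Inf) {
  in_trial <- which(frames$trial == trial)
  sp <- in_trial[frames$label[in_trial] %in% 1]
  ns <- length(sp)
  if (ns == 0) {
    warning(sprintf("balance_trial: trial %s has no speech frames; skipped", trial))
    return(integer(0))
  }
  t_on <- min(frames$time[sp])
  t_off <- max(frames$time[sp])
  sil <- in_trial[frames$label[in_trial] %in% -1]
  before <- sil[frames$time[sil] < t_on]
  after <- sil[frames$time[sil] > t_off & frames$time[sil] < next_trial_start]
  before <- before[order(frames$time[before])]
  after <- after[order(frames$time[after])]
  if (length(before) + length(after) < ns) {
    stop(sprintf(
      "balance_trial: trial %s has %d speech frames but only %d silence frames",
      trial, ns, length(before) + length(after)
    ))
  }
  n_after <- min(ns %/% 2, length(after))
  n_before <- ns - n_after
  if (n_before > length(before)) { # not enough before: push back after
    n_after <- n_after + (n_before - length(before))
    n_before <- length(before)
  }
  sel_before <- if (n_before > 0) utils::tail(before, n_before) else integer(0)
  sel_after <- if (n_after > 0) utils::head(after, n_after) else integer(0)
  sort(c(sel_before, sp, sel_after))
}

#' Balance every trial of a labeled frame dataset
#'
#' Applies [balance_trial()] to each trial in turn and returns the
#' concatenated balanced dataset, which then holds exactly as many +1 as
#' -1 frames overall and per trial.
#'
#' @param frames labeled `frame_dataset`.
#' @param trials trial table supplying the per-trial ordering (used to find
#'   each trial's successor start time); defaults to trial order by id.
#' @return a balanced `frame_dataset`.
#' @export
balance_dataset <- function(frames, trials = NULL) {
  ids <- sort(unique(frames$trial))
  if (!is.null(trials)) {
    trials <- trials[order(trials$trial_start), ]
    starts <- c(trials$trial_start[-1], Inf)
    names(starts) <- trials$trial
  } else {
    starts <- rep(Inf, length(ids))
    names(starts) <- ids
  }
  sel <- unlist(lapply(ids, function(tr) {
    balance_trial(frames, tr, starts[[as.character(tr)]])
  }))
  subset_frames(frames, sel)
}

#' Consensus surrogate speech timing for imagined trials
#'
#' Imagined speech has no behavioral timing, so the timing is borrowed from
#' the performed trials: align all performed trials at the go cue, average
#' their 0/1 speech labels per frame, and call *speech* the maximal
#' contiguous span where the average exceeds 0.9 (strictly). *Silence* is
#' taken before the go cue where the average is below 0.1 (strictly), plus
#' at most 500 ms at the very end of the trial where it is below 0.1 —
#' capped to favor pre-go-cue data, whose probability of containing
#' imagined speech is essentially zero. Post-go-cue frames satisfying
#' neither rule are discarded as ambiguous. By construction this
#' overestimates the onset delay and underestimates the offset.
#'
#' @param label_matrix trials x frames matrix of 0/1 performed-speech
#'   labels, columns aligned at the go cue.
#' @param go_cue_frame index of the first frame at/after the go cue
#'   (frames before it are pre-go-cue).
#' @param fs frame rate in Hz (for the 500 ms end cap).
#' @param end_max maximal end-of-trial silence to keep (s).
#' @return list of class `surrogate_timing`: `speech`, `silence_pre`,
#'   `silence_end`, `discarded` (frame index vectors), `t_on`, `t_off`
#'   (go-cue-relative window in seconds, frame 0 = go cue).
#' @export
surrogate_imagined_timing <- function(label_matrix, go_cue_frame, fs = 256,
                                      end_max = 0.5) {
  if (nrow(label_matrix) < 2) {
    stop("surrogate_imagined_timing: need at least 2 performed trials")
  }
  avg <- colMeans(label_matrix)
  nf <- length(avg)
  hi <- avg > 0.9
  if (!any(hi)) stop("surrogate_imagined_timing: no consensus speech window")
  runs <- rle(hi)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]
  speech <- starts[best]:ends[best]

  pre <- seq_len(go_cue_frame - 1)
  silence_pre <- pre[avg[pre] < 0.1]
  cap <- round(end_max * fs)
  tail_idx <- nf
  silence_end <- integer(0)
  while (tail_idx > max(speech) && avg[tail_idx] < 0.1 &&
         length(silence_end) < cap) {
    silence_end <- c(tail_idx, silence_end)
    tail_idx <- tail_idx - 1
  }
  discarded <- setdiff(seq_len(nf), c(speech, silence_pre, silence_end))

  structure(
    list(
      speech = speech, silence_pre = silence_pre, silence_end = silence_end,
      discarded = discarded,
      t_on = (min(speech) - go_cue_frame) / fs,
      t_off = (max(speech) - go_cue_frame + 1) / fs,
      end_silence_s = length(silence_end) / fs
    ),
    class = "surrogate_timing"
  )
}

#' Passive (cue-centered) frame dataset
#'
#' Frames of imagined trials inside a window of `width` seconds centered
#' at the task cue, all labeled -1: no intentional imagined speech is
#' assumed there, so the accuracy on this set reads as a specificity. It is
#' used to reject electrodes that respond to the visual cue rather than to
#' speech.
#'
#' @param frames a `frame_dataset`.
#' @param cue_times data.frame with columns `trial`, `cue_onset`.
#' @param width window width in seconds (default 4).
#' @return a `frame_dataset` with all labels -1.
#' @export
passive_dataset <- function(frames, cue_times, width = 4) {
  cue <- cue_times$cue_onset[match(frames$trial, cue_times$trial)]
  keep <- which(!is.na(cue) &
                frames$time >= cue - width / 2 & frames$time < cue + width / 2)
  out <- subset_frames(frames, keep)
  out$label <- rep(-1, length(keep))
  out
}

#' Passive-dataset exclusion rule
#'
#' If an electrode's accuracy on the passive (cue-centered) dataset is
#' strictly below 50%, its reported score is set to 50% and it is flagged
#' as excluded; otherwise the active accuracy is reported unchanged.
#'
#' @param active_acc accuracy on the active dataset (percent).
#' @param passive_acc accuracy on the passive dataset (percent).
#' @return list with `score` (percent) and `excluded` (logical).
#' @export
apply_passive_exclusion <- function(active_acc, passive_acc) {
  stopifnot(active_acc >= 0, active_acc <= 100,
            passive_acc >= 0, passive_acc <= 100)
  if (passive_acc < 50) {
    list(score = 50, excluded = TRUE)
  } else {
    list(score = active_acc, excluded = FALSE)
  }
}

#' Apply surrogate timing to imagined-trial frames
#'
#' Maps a go-cue-relative [surrogate_imagined_timing()] result onto the
#' frames of imagined trials: +1 inside the surrogate speech window, -1 in
#' the pre-go-cue silence (where within the trial) and in at most 500 ms of
#' end-of-trial silence, `NA` (discarded) elsewhere.
#'
#' @param frames a `frame_dataset` covering imagined trials.
#' @param trials observable trial table rows for those trials (needs
#'   `trial`, `go_onset`, `trial_start`, `trial_end`).
#' @param timing a `surrogate_timing`.
#' @return `frames` with labels filled (`NA` = discarded).
#' @export
surrogate_frame_labels <- function(frames, trials, timing) {
  lab <- rep(NA_real_, length(frames$time))
  for (i in seq_len(nrow(trials))) {
    tr <- trials$trial[i]
    go <- trials$go_onset[i]
    in_tr <- frames$trial == tr
    rel <- frames$time - go
    speech <- in_tr & rel >= timing$t_on & rel <= timing$t_off
    pre <- in_tr & frames$time < go & frames$time >= trials$trial_start[i]
    end_sil <- in_tr & frames$time >= trials$trial_end[i] - timing$end_silence_s
    lab[pre] <- -1
    lab[end_sil] <- -1
    lab[speech] <- 1
  }
  frames$label <- lab
  frames
}
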