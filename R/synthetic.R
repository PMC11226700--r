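# Synthetic paradigm-structured ECoG with known ground truth.
#
# The generator emulates a cued sentence task: fixation/cue (1 s), a
# preparation window (2 s plus up to 1 s of jitter, to suppress expectation
# effects), a go cue, then a few seconds of performed / perceived / imagined
# speech. Each electrode is a sum of seven band-limited unit-variance noise
# carriers whose amplitude is modulated around the true speech window, plus
# optional 50 Hz line noise and a cue-locked broadband burst.

#' Paradigm configuration for the synthetic task
#'
#' Defaults follow the recorded task: a 1 s task cue, a 2 s preparation
#' window with up to 1 s of uniform jitter, 20 trials per speech mode and a
#' 256 Hz sampling rate. Speech durations emulate short controlled
#' sentences (mean 2.5 s) and voice onset lags the go cue by roughly half a
#' second.
#'
#' @param n_trials_per_mode trials per speech mode.
#' @param cue_duration task-cue display time (s).
#' @param prep_duration preparation window base duration (s).
#' @param prep_jitter_max maximal uniform jitter added to the preparation
#'   window (s); must not exceed `prep_duration`.
#' @param speech_duration_mean,speech_duration_sd sentence speech duration (s).
#' @param onset_delay_mean,onset_delay_sd speech-onset delay after the go
#'   cue (s).
#' @param inter_trial_gap silence kept after the speech offset before the
#'   next trial starts (s).
#' @param sampling_rate Hz.
#' @return a validated list of class `paradigm_config`.
#' @export
paradigm_config <- function(n_trials_per_mode = 20,
                            cue_duration = 1,
                            prep_duration = 2,
                            prep_jitter_max = 1,
                            speech_duration_mean = 2.5,
                            speech_duration_sd = 0.4,
                            onset_delay_mean = 0.5,
                            onset_delay_sd = 0.15,
                            inter_trial_gap = 2,
                            sampling_rate = 256) {
  cfg <- list(
    n_trials_per_mode = n_trials_per_mode,
    cue_duration = cue_duration,
    prep_duration = prep_duration,
    prep_jitter_max = prep_jitter_max,
    speech_duration_mean = speech_duration_mean,
    speech_duration_sd = speech_duration_sd,
    onset_delay_mean = onset_delay_mean,
    onset_delay_sd = onset_delay_sd,
    inter_trial_gap = inter_trial_gap,
    sampling_rate = sampling_rate
  )
  for (f in c("n_trials_per_mode", "cue_duration", "prep_duration",
              "speech_duration_mean", "onset_delay_mean", "inter_trial_gap",
              "sampling_rate")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop(sprintf("paradigm_config: field '%s' must be a positive number", f))
    }
  }
  for (f in c("prep_jitter_max", "speech_duration_sd", "onset_delay_sd")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      stop(sprintf("paradigm_config: field '%s' must be non-negative", f))
    }
  }
  if (cfg$prep_jitter_max > cfg$prep_duration) {
    stop("paradigm_config: field 'prep_jitter_max' must not exceed 'prep_duration'")
  }
  class(cfg) <- "paradigm_config"
  cfg
}

#' Speech modes known to the pipeline
#' @return character vector.
#' @export
speech_modes <- function() c("performed", "perceived", "imagined")

#' Generate the trial layout of the cued-sentence paradigm
#'
#' Lays out one trial per (sentence, mode) combination in randomized order.
#' Returns both the *observable* trial table — in which imagined trials
#' carry no speech on/offset, since covert speech produces no behavioral
#' timing — and a separate ground-truth table holding the true windows for
#' every trial. Downstream analysis code must only ever see the former.
#'
#' @param cfg a `paradigm_config`.
#' @param seed integer seed; the same seed reproduces the layout exactly.
#' @param modes which speech modes to include.
#' @return list with `trials` (observable data.frame: trial, sentence, mode,
#'   trial_start, cue_onset, go_onset, speech_onset, speech_offset,
#'   trial_end; times in seconds from recording start) and `ground_truth`
#'   (data.frame: trial, mode, onset, offset, both absolute and go-relative).
#' @export
make_paradigm <- function(cfg = paradigm_config(), seed = 1,
                          modes = speech_modes()) {
  stopifnot(inherits(cfg, "paradigm_config"))
  bad <- setdiff(modes, speech_modes())
  if (length(bad)) stop("make_paradigm: unknown mode(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  grid <- expand.grid(
    sentence = seq_len(cfg$n_trials_per_mode), mode = modes,
    stringsAsFactors = FALSE
  )
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  nt <- nrow(grid)

  lead_in <- 2 # seconds of silence before the first trial / after the last
  t0 <- lead_in
  rows <- vector("list", nt)
  for (i in seq_len(nt)) {
    prep <- cfg$prep_duration + stats::runif(1, 0, cfg$prep_jitter_max)
    go <- t0 + cfg$cue_duration + prep
    onset <- go + max(0.05, stats::rnorm(1, cfg$onset_delay_mean, cfg$onset_delay_sd))
    offset <- onset + max(0.3, stats::rnorm(1, cfg$speech_duration_mean, cfg$speech_duration_sd))
    t_end <- offset + cfg$inter_trial_gap
    rows[[i]] <- data.frame(
      trial = i, sentence = grid$sentence[i], mode = grid$mode[i],
      trial_start = t0, cue_onset = t0, go_onset = go,
      speech_onset = onset, speech_offset = offset, trial_end = t_end,
      stringsAsFactors = FALSE
    )
    t0 <- t_end
  }
  trials <- do.call(rbind, rows)

  ground_truth <- data.frame(
    trial = trials$trial, mode = trials$mode,
    onset = trials$speech_onset, offset = trials$speech_offset,
    onset_go = trials$speech_onset - trials$go_onset,
    offset_go = trials$speech_offset - trials$go_onset,
    stringsAsFactors = FALSE
  )
  hide <- trials$mode == "imagined"
  trials$speech_onset[hide] <- NA_real_
  trials$speech_offset[hide] <- NA_real_
  list(trials = trials, ground_truth = ground_truth)
}

#' Region- and mode-specific band-modulation defaults
#'
#' Fractional amplitude change of each band's carrier during speech,
#' emulating the qualitative physiology the detector is meant to pick up:
#' motor-like electrodes raise gamma and depress low frequencies in every
#' speech mode (weakest for perceived speech); temporal-like electrodes
#' raise gamma for performed and perceived speech but show *no* gamma
#' change for imagined speech while their low-frequency modulation persists
#' in all modes; "other" electrodes carry no speech modulation at all.
#'
#' Magnitudes are tuning knobs of the simulator, not estimates of any
#' patient's physiology.
#'
#' @param region `"motor"`, `"temporal"` or `"other"`.
#' @param mode `"performed"`, `"perceived"` or `"imagined"`.
#' @return named numeric vector of length 7 (one entry per band).
#' @export
default_profiles <- function(region = c("motor", "temporal", "other"),
                             mode = speech_modes()) {
  region <- match.arg(region)
  mode <- match.arg(mode, speech_modes())
  bands <- band_set()$band
  m <- switch(region,
    motor = {
      base <- c(-0.35, -0.3, -0.2, -0.2, 0.1, 0.5, 0.5)
      scale <- c(performed = 1, perceived = 0.6, imagined = 0.8)[[mode]]
      base * scale
    },
    temporal = {
      low <- c(-0.35, -0.35, -0.25, -0.2, -0.15)
      gamma <- if (mode == "imagined") c(0, 0) else c(0.45, 0.45)
      c(low, gamma)
    },
    other = rep(0, 7)
  )
  names(m) <- bands
  m
}

#' Construct an electrode simulation profile
#'
#' @param electrode electrode id.
#' @param grid grid id (used by common-average referencing).
#' @param region `"motor"`, `"temporal"` or `"other"`; fills per-mode
#'   modulation defaults via [default_profiles()] unless `modulation` is
#'   given.
#' @param modulation optional 7 x 3 matrix (bands x modes, columns named
#'   performed/perceived/imagined) of fractional amplitude changes; every
#'   entry must be > -1.
#' @param baseline_amp optional length-7 vector of baseline band amplitudes
#'   (microvolts); defaults to a 1/f profile `amp_scale / f_center`.
#' @param amp_scale scale of the default 1/f amplitude profile.
#' @param cue_response_gain gain of a 300 ms broadband burst locked to the
#'   task cue (models visual cue responses; 0 disables).
#' @param line_noise_amp amplitude of 50 Hz line noise (microvolts).
#' @return list of class `electrode_profile`.
#' @export
electrode_profile <- function(electrode, grid = 1, region = "other",
                              modulation = NULL, baseline_amp = NULL,
                              amp_scale = 50, cue_response_gain = 0,
                              line_noise_amp = 0) {
  bands <- band_set()
  if (is.null(modulation)) {
    modulation <- sapply(speech_modes(), function(m) default_profiles(region, m))
  }
  modulation <- as.matrix(modulation)
  if (nrow(modulation) != 7 || ncol(modulation) != 3) {
    stop("electrode_profile: modulation must be a 7 x 3 (band x mode) matrix")
  }
  colnames(modulation) <- speech_modes()
  rownames(modulation) <- bands$band
  if (any(modulation <= -1)) {
    stop("electrode_profile: modulation entries must be > -1 (amplitude stays positive)")
  }
  if (is.null(baseline_amp)) {
    fc <- sqrt(bands$low * bands$high)
    baseline_amp <- amp_scale / fc
  }
  if (length(baseline_amp) != 7 || any(baseline_amp < 0)) {
    stop("electrode_profile: baseline_amp must be 7 non-negative amplitudes")
  }
  names(baseline_amp) <- bands$band
  structure(
    list(
      electrode = electrode, grid = grid, region = region,
      modulation = modulation, baseline_amp = baseline_amp,
      cue_response_gain = cue_response_gain, line_noise_amp = line_noise_amp
    ),
    class = "electrode_profile"
  )
}

# Smoothed 0/1 speech indicator with raised-cosine ramps (ramp s wide),
# evaluated at sample times t for a window [on, off].
speech_ramp <- function(t, on, off, ramp = 0.25) {
  s <- numeric(length(t))
  r2 <- ramp / 2
  rise <- t >= on - r2 & t < on + r2
  fall <- t > off - r2 & t <= off + r2
  mid <- t >= on + r2 & t <= off - r2
  s[mid] <- 1
  s[rise] <- 0.5 * (1 - cos(pi * (t[rise] - (on - r2)) / ramp))
  s[fall] <- 0.5 * (1 + cos(pi * (t[fall] - (off - r2)) / ramp))
  s
}

#' Synthesize a multichannel ECoG recording from a trial layout
#'
#' Each channel is `sum_b a_b (1 + m_b(mode) s(t)) n_b(t)` where `n_b` is
#' unit-variance Gaussian noise band-passed into band `b` with the same
#' 4th-order zero-phase Butterworth used by the analysis filter bank, and
#' `s(t)` is the ground-truth speech indicator smoothed with 250 ms
#' raised-cosine ramps. Line noise and a cue-locked broadband burst are
#' added per the electrode profile.
#'
#' @param paradigm result of [make_paradigm()] (uses both the observable
#'   trials and the ground truth).
#' @param profiles list of [electrode_profile()] objects.
#' @param seed integer seed; output is reproducible given (paradigm,
#'   profiles, seed).
#' @param fs sampling rate in Hz.
#' @param ramp speech-indicator ramp time (s).
#' @return an [ecog_recording()].
#' @export
synthesize_ecog <- function(paradigm, profiles, seed = 1, fs = 256,
                            ramp = 0.25) {
  trials <- paradigm$trials
  gt <- paradigm$ground_truth
  if (length(profiles) == 0) stop("synthesize_ecog: profiles must be non-empty")
  ord <- order(trials$trial_start)
  if (any(diff(trials$trial_end[ord]) <= 0) ||
      any(trials$trial_start[ord][-1] < trials$trial_end[ord][-nrow(trials)] - 1e-9)) {
    stop("synthesize_ecog: overlapping trials in layout")
  }
  set.seed(seed)
  total <- max(trials$trial_end) + 2
  n <- ceiling(total * fs)
  t <- (seq_len(n) - 1) / fs
  bands <- band_set(fs)

  # global speech indicator and per-sample mode index (from ground truth)
  s_t <- numeric(n)
  mode_idx <- integer(n) # 0 = outside any trial
  modes <- speech_modes()
  for (i in seq_len(nrow(gt))) {
    win <- which(t >= gt$onset[i] - ramp & t <= gt$offset[i] + ramp)
    s_t[win] <- s_t[win] + speech_ramp(t[win], gt$onset[i], gt$offset[i], ramp)
    tr <- trials[trials$trial == gt$trial[i], ]
    span <- which(t >= tr$trial_start & t < tr$trial_end)
    mode_idx[span] <- match(gt$mode[i], modes)
  }
  s_t <- pmin(s_t, 1)

  filters <- lapply(seq_len(nrow(bands)), function(b) {
    butter_sos(4, c(bands$low[b], bands$high[b]), fs, "pass")
  })

  sig <- matrix(0, nrow = length(profiles), ncol = n)
  for (e in seq_along(profiles)) {
    pr <- profiles[[e]]
    x <- numeric(n)
    for (b in seq_len(nrow(bands))) {
      a <- pr$baseline_amp[b]
      if (a == 0) next
      nb <- filtfilt_sos(filters[[b]], stats::rnorm(n),
                         pad = min(n - 1, ceiling(3 * fs / bands$low[b])))
      nb <- nb / stats::sd(nb)
      mod <- rep(1, n)
      active <- mode_idx > 0
      mod[active] <- 1 + pr$modulation[b, mode_idx[active]] * s_t[active]
      x <- x + a * mod * nb
    }
    if (pr$line_noise_amp > 0) {
      x <- x + pr$line_noise_amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    }
    if (pr$cue_response_gain > 0) {
      for (cue in trials$cue_onset) {
        win <- which(t >= cue & t < cue + 0.3)
        if (!length(win)) next
        env <- 0.5 * (1 - cos(2 * pi * seq_along(win) / length(win)))
        x[win] <- x[win] + pr$cue_response_gain * 30 * env * stats::rnorm(length(win))
      }
    }
    sig[e, ] <- x
  }

  channels <- data.frame(
    channel = vapply(profiles, function(p) as.character(p$electrode), ""),
    grid = vapply(profiles, function(p) p$grid, profiles[[1]]$grid),
    region = vapply(profiles, function(p) p$region, ""),
    stringsAsFactors = FALSE
  )
  ecog_recording(sig, fs, channels)
}
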