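# High-level orchestration: raw recording -> envelopes -> labeled balanced
# frame datasets per speech mode -> detection, ensembles, transfer and
# permutation statistics, with everything written as TSV/JSON.

#' Standard preprocessing chain
#'
#' Artifact screening (1 mV limit), per-grid common-average referencing and
#' zero-phase line-noise removal, in that order. Referencing a
#' single-channel grid would zero it out by definition, so grids left with
#' only one retained channel are kept unreferenced (with a message).
#'
#' @param rec raw `ecog_recording`.
#' @param limit artifact amplitude limit (microvolts).
#' @param line_freq line frequency in Hz; `NA` skips the notch.
#' @return preprocessed `ecog_recording` (rejected channels dropped).
#' @export
preprocess_recording <- function(rec, limit = 1000, line_freq = 50) {
  keep <- screen_artifacts(rec, limit)
  if (!any(keep)) stop("preprocess_recording: all channels rejected")
  rec <- subset_channels(rec, keep)
  sizes <- table(rec$channels$grid)
  multi <- names(sizes)[sizes >= 2]
  if (length(multi) < length(sizes)) {
    message("preprocess_recording: grid(s) with a single retained channel ",
            "left unreferenced: ",
            paste(setdiff(names(sizes), multi), collapse = ", "))
  }
  if (length(multi)) {
    idx <- rec$channels$grid %in% multi
    sub <- common_average_reference(subset_channels(rec, idx))
    rec$signals[idx, ] <- sub$signals
  }
  if (!is.na(line_freq)) rec <- notch_line_noise(rec, line_freq)
  rec
}

#' Go-cue-aligned 0/1 label matrix of the performed trials
#'
#' Builds the trials x frames matrix that feeds
#' [surrogate_imagined_timing()]: a common go-cue-relative time grid
#' covering the span shared by all performed trials, with 1 wherever the
#' trial's observable speech window covers the frame.
#'
#' @param trials observable trial table rows of the performed trials.
#' @param fs sampling rate in Hz.
#' @param stride frame stride in samples.
#' @return list with `labels` (matrix), `go_cue_frame`, `frame_fs`, `rel_time`.
#' @export
performed_label_matrix <- function(trials, fs, stride = 1) {
  stopifnot(nrow(trials) >= 2, all(!is.na(trials$speech_onset)))
  frame_fs <- fs / stride
  pre <- min(trials$go_onset - trials$trial_start)
  post <- min(trials$trial_end - trials$go_onset)
  rel <- seq(-pre, post - 1 / frame_fs, by = 1 / frame_fs)
  lab <- t(vapply(seq_len(nrow(trials)), function(i) {
    on <- trials$speech_onset[i] - trials$go_onset[i]
    off <- trials$speech_offset[i] - trials$go_onset[i]
    as.numeric(rel >= on & rel <= off)
  }, numeric(length(rel))))
  list(
    labels = lab,
    go_cue_frame = which(rel >= 0)[1],
    frame_fs = frame_fs,
    rel_time = rel
  )
}

#' Build the labeled, balanced frame dataset of one electrode and mode
#'
#' Performed and perceived trials are labeled from their observable speech
#' windows and balanced per trial. Imagined trials are labeled with the
#' consensus surrogate timing derived from the performed trials (ambiguous
#' frames dropped), then balanced the same way.
#'
#' @param env an `envelope_tensor` of the preprocessed recording.
#' @param channel channel id or index.
#' @param paradigm result of [make_paradigm()].
#' @param mode speech mode to extract.
#' @param stride frame stride in samples.
#' @param band_subset feature band subset.
#' @return a balanced, labeled `frame_dataset`.
#' @export
build_mode_dataset <- function(env, channel, paradigm,
                               mode = c("performed", "perceived", "imagined"),
                               stride = 1,
                               band_subset = c("full", "low", "gamma")) {
  mode <- match.arg(mode)
  band_subset <- match.arg(band_subset)
  trials <- paradigm$trials
  sel <- trials[trials$mode == mode, , drop = FALSE]
  if (nrow(sel) == 0) stop("build_mode_dataset: no trials of mode ", mode)
  frames <- build_features(env, channel, trial_frames(sel, env$fs, stride),
                           band_subset)
  if (mode %in% c("performed", "perceived")) {
    windows <- data.frame(trial = sel$trial, onset = sel$speech_onset,
                          offset = sel$speech_offset)
    frames <- frames_to_labels(frames, windows)
  } else {
    perf <- trials[trials$mode == "performed", , drop = FALSE]
    lm <- performed_label_matrix(perf, env$fs, stride)
    timing <- surrogate_imagined_timing(lm$labels, lm$go_cue_frame,
                                        fs = lm$frame_fs)
    frames <- surrogate_frame_labels(frames, sel, timing)
  }
  balance_dataset(frames, sel)
}

#' Passive-window evaluation of an imagined-speech detector
#'
#' Trains one detector on the full active imagined dataset and scores it on
#' the cue-centered passive frames (all assumed silent), returning the
#' passive accuracy (a specificity).
#'
#' @param active balanced imagined `frame_dataset` (training set).
#' @param env,channel,paradigm,stride,band_subset as in
#'   [build_mode_dataset()].
#' @param width passive window width (s).
#' @return passive accuracy in percent.
#' @export
passive_accuracy <- function(active, env, channel, paradigm, stride = 1,
                             band_subset = "full", width = 4) {
  sel <- paradigm$trials[paradigm$trials$mode == "imagined", , drop = FALSE]
  frames <- build_features(env, channel, trial_frames(sel, env$fs, stride),
                           band_subset)
  pass <- passive_dataset(frames, sel[, c("trial", "cue_onset")], width)
  acz <- zscore_features(active)
  paz <- zscore_features(active, pass)
  model <- fit_detector(acz$X, acz$label, band_subset)
  dec <- predict_frames(model, paz$X)$decision
  100 * mean(dec == pass$label)
}

#' Run the end-to-end pipeline on synthetic data
#'
#' Simulates the paradigm and recording, preprocesses, extracts envelopes,
#' builds labeled datasets per speech mode, and evaluates: per-electrode
#' leave-one-trial-out accuracies for each band subset, activation
#' patterns, a permutation test for the best electrode, the
#' multi-electrode accuracy-versus-k curve, and the cross-mode transfer
#' matrix of the best electrode. All tables are written as TSV plus a JSON
#' summary carrying the seed and a hash of the configuration.
#'
#' @param config a list (or path to a JSON/YAML file) with any of:
#'   `seed`, `n_trials_per_mode`, `stride`, `n_perm`, `max_electrodes`,
#'   `band_subsets`, `modes`, and `electrodes` (data.frame with columns
#'   `electrode`, `grid`, `region`, and optionally `line_noise_amp`,
#'   `cue_response_gain`).
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return the results list, invisibly when writing.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("run_pipeline: reading YAML configs requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  def <- list(
    seed = 1, n_trials_per_mode = 20, stride = 8, n_perm = 200,
    max_electrodes = NULL, band_subsets = c("full", "low", "gamma"),
    modes = speech_modes(),
    electrodes = data.frame(
      electrode = c("M1", "T1", "O1"), grid = c("A", "B", "A"),
      region = c("motor", "temporal", "other"),
      line_noise_amp = 5, cue_response_gain = c(0, 0, 0.5)
    )
  )
  cfg <- def
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  el <- as.data.frame(cfg$electrodes)
  if (is.null(el$line_noise_amp)) el$line_noise_amp <- 0
  if (is.null(el$cue_response_gain)) el$cue_response_gain <- 0

  pc <- paradigm_config(n_trials_per_mode = cfg$n_trials_per_mode)
  paradigm <- make_paradigm(pc, seed = cfg$seed, modes = cfg$modes)
  profiles <- lapply(seq_len(nrow(el)), function(i) {
    electrode_profile(el$electrode[i], el$grid[i], el$region[i],
                      line_noise_amp = el$line_noise_amp[i],
                      cue_response_gain = el$cue_response_gain[i])
  })
  rec <- synthesize_ecog(paradigm, profiles, seed = cfg$seed + 1)
  rec <- preprocess_recording(rec)
  env <- extract_envelopes(rec)

  chans <- rec$channels$channel
  acc_rows <- list()
  patterns <- list()
  datasets <- list() # [[mode]][[channel]] full-band balanced dataset
  for (mode in cfg$modes) {
    datasets[[mode]] <- list()
    for (ch in chans) {
      ds <- build_mode_dataset(env, ch, paradigm, mode, cfg$stride, "full")
      datasets[[mode]][[ch]] <- ds
      for (bs in cfg$band_subsets) {
        cv <- loto_cv(restrict_bands(ds, bs))
        acc_rows[[length(acc_rows) + 1]] <- data.frame(
          electrode = ch, mode = mode, bands = bs,
          mean_acc = cv$mean_acc, n_trials = cv$n_folds
        )
        if (bs == "full") patterns[[paste(ch, mode, sep = ".")]] <- cv$pattern
      }
    }
  }
  acc_tab <- do.call(rbind, acc_rows)

  # permutation test on the best full-band electrode of each mode
  perm <- list()
  for (mode in cfg$modes) {
    sub <- acc_tab[acc_tab$mode == mode & acc_tab$bands == "full", ]
    best <- sub$electrode[which.max(sub$mean_acc)]
    pt <- permutation_test_cv(datasets[[mode]][[best]],
                              n_perm = cfg$n_perm, seed = cfg$seed + 2)
    perm[[mode]] <- list(electrode = best, observed = pt$observed,
                         p_value = pt$p_value, n_perm = pt$n_perm)
  }

  # multi-electrode curve on the first mode
  K <- if (is.null(cfg$max_electrodes)) length(chans) else
    min(cfg$max_electrodes, length(chans))
  mode1 <- cfg$modes[1]
  ens <- ensemble_cv(unname(datasets[[mode1]]), K)
  opt <- select_optimal_count(ens)
  curve <- data.frame(k = seq_len(K), mean_acc = opt$mean_acc)

  # cross-mode transfer matrix for the best electrode of the first mode
  transfer_tab <- NULL
  if (length(cfg$modes) > 1) {
    best1 <- perm[[mode1]]$electrode
    cells <- list()
    for (mtr in cfg$modes) for (mte in cfg$modes) {
      tv <- transfer_evaluate(datasets[[mtr]][[best1]], datasets[[mte]][[best1]])
      cells[[length(cells) + 1]] <- data.frame(
        electrode = best1, train = mtr, test = mte, mean_acc = tv$mean_acc
      )
    }
    transfer_tab <- do.call(rbind, cells)
  }

  results <- list(
    config = cfg, accuracy = acc_tab, patterns = patterns,
    permutation = perm, ensemble_curve = curve, k_opt = opt$k_opt,
    transfer = transfer_tab, paradigm = paradigm
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
    cfg_hash <- unname(tools::md5sum(cfg_path))
    wr <- function(df, name) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    stamp <- function(df) {
      df$seed <- cfg$seed
      df$config_hash <- cfg_hash
      df
    }
    wr(stamp(acc_tab), "accuracy.tsv")
    wr(stamp(curve), "ensemble_curve.tsv")
    if (!is.null(transfer_tab)) wr(stamp(transfer_tab), "transfer.tsv")
    pat_long <- do.call(rbind, lapply(names(patterns), function(k) {
      p <- patterns[[k]]
      data.frame(
        key = k, band = rep(rownames(p), times = ncol(p)),
        lag = rep(colnames(p), each = nrow(p)), value = as.vector(p)
      )
    }))
    wr(stamp(pat_long), "activation_patterns.tsv")
    write_events_tsv(paradigm$trials, file.path(out_dir, "events.tsv"))
    write_ground_truth_tsv(paradigm$ground_truth,
                           file.path(out_dir, "ground_truth.tsv"))
    jsonlite::write_json(
      list(seed = cfg$seed, config_hash = cfg_hash, permutation = perm,
           k_opt = opt$k_opt),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    return(invisible(results))
  }
  results
}
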