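test_that("paradigm layout: counts, ordering, hidden imagined timing", {
  par <- make_paradigm(paradigm_config(n_trials_per_mode = 20), seed = 1)
  tr <- par$trials
  expect_equal(nrow(tr), 60)
  expect_equal(unname(table(tr$mode)[speech_modes()]), rep(20L, 3),
               ignore_attr = TRUE)
  # event times strictly increasing within each trial
  for (i in seq_len(nrow(tr))) {
    tms <- c(tr$cue_onset[i], tr$go_onset[i], tr$trial_end[i])
    expect_true(all(diff(tms) > 0))
  }
  # imagined trials expose no behavioral timing; ground truth still has it
  im <- tr$mode == "imagined"
  expect_true(all(is.na(tr$speech_onset[im])))
  expect_true(all(is.na(tr$speech_offset[im])))
  gt <- par$ground_truth
  expect_false(anyNA(gt$onset))
  expect_true(all(gt$onset < gt$offset))
})

test_that("zero preparation jitter makes every go-cue latency identical", {
  cfg <- paradigm_config(n_trials_per_mode = 5, prep_jitter_max = 0)
  par <- make_paradigm(cfg, seed = 3)
  lat <- par$trials$go_onset - par$trials$cue_onset
  expect_equal(max(lat) - min(lat), 0)
})

test_that("same seed reproduces the paradigm and the recording exactly", {
  cfg <- paradigm_config(n_trials_per_mode = 3)
  p1 <- make_paradigm(cfg, seed = 9)
  p2 <- make_paradigm(cfg, seed = 9)
  expect_identical(p1, p2)
  profs <- list(electrode_profile("E1", "A", "motor", line_noise_amp = 3))
  r1 <- synthesize_ecog(p1, profs, seed = 4)
  r2 <- synthesize_ecog(p2, profs, seed = 4)
  expect_identical(r1$signals, r2$signals)
  r3 <- synthesize_ecog(p1, profs, seed = 5)
  expect_false(identical(r1$signals, r3$signals))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(paradigm_config(cue_duration = -1), "cue_duration")
  expect_error(paradigm_config(prep_jitter_max = 3, prep_duration = 2),
               "prep_jitter_max")
  expect_error(paradigm_config(sampling_rate = 0), "sampling_rate")
})

test_that("default modulation profiles encode the region/mode physiology", {
  # temporal imagined: no gamma modulation, low bands still active
  ti <- default_profiles("temporal", "imagined")
  expect_equal(unname(ti[c("lowgamma", "highgamma")]), c(0, 0))
  expect_true(all(ti[1:5] != 0))
  # temporal performed/perceived: gamma up
  expect_gt(default_profiles("temporal", "performed")[["highgamma"]], 0)
  expect_gt(default_profiles("temporal", "perceived")[["lowgamma"]], 0)
  # motor: same signs in every mode, gamma up, delta/theta down
  mp <- default_profiles("motor", "performed")
  for (m in c("perceived", "imagined")) {
    expect_equal(sign(default_profiles("motor", m)), sign(mp))
  }
  expect_true(all(mp[c("lowgamma", "highgamma")] > 0))
  expect_true(all(mp[c("delta", "theta")] < 0))
  expect_equal(unname(default_profiles("other", "imagined")), rep(0, 7))
  expect_error(default_profiles("occipital", "performed"))
})

test_that("no modulation means no speech/silence power difference", {
  cfg <- paradigm_config(n_trials_per_mode = 40)
  par <- make_paradigm(cfg, seed = 21, modes = "performed")
  prof <- electrode_profile("E1", "A", "other") # all m = 0
  rec <- synthesize_ecog(par, list(prof), seed = 22)
  x <- rec$signals[1, ]
  fs <- rec$fs
  gt <- par$ground_truth
  sp <- unlist(lapply(seq_len(nrow(gt)), function(i) {
    seq(round((gt$onset[i] + 0.3) * fs), round((gt$offset[i] - 0.3) * fs))
  }))
  tr <- par$trials
  sil <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    seq(round(tr$trial_start[i] * fs), round((tr$go_onset[i] - 0.2) * fs))
  }))
  expect_equal(stats::var(x[sp]) / stats::var(x[sil]), 1, tolerance = 0.05)
})

test_that("injected modulation produces the predicted power ratio (PSD oracle)", {
  # single active band with m = 0.5: speech/silence power ratio (1.5)^2
  cfg <- paradigm_config(n_trials_per_mode = 100)
  par <- make_paradigm(cfg, seed = 31, modes = "performed")
  mod <- matrix(0, 7, 3)
  mod[5, ] <- 0.5 # beta2
  amp <- c(0, 0, 0, 0, 10, 0, 0)
  prof <- electrode_profile("E1", "A", modulation = mod, baseline_amp = amp)
  rec <- synthesize_ecog(par, list(prof), seed = 32)
  x <- rec$signals[1, ]
  fs <- rec$fs
  gt <- par$ground_truth
  tr <- par$trials
  pow <- function(idx) mean(x[idx]^2)
  sp <- unlist(lapply(seq_len(nrow(gt)), function(i) {
    seq(round((gt$onset[i] + 0.3) * fs), round((gt$offset[i] - 0.3) * fs))
  }))
  sil <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    seq(round(tr$trial_start[i] * fs), round((tr$go_onset[i] - 0.2) * fs))
  }))
  expect_equal(pow(sp) / pow(sil), 2.25, tolerance = 0.1 * 2.25)
})

test_that("line-noise control: absent at amp 0, present when injected", {
  cfg <- paradigm_config(n_trials_per_mode = 4)
  par <- make_paradigm(cfg, seed = 41, modes = "performed")
  peak_db <- function(rec) {
    x <- rec$signals[1, ]
    n <- 2^floor(log2(length(x)))
    sp <- Mod(stats::fft(x[1:n]))^2
    f <- (seq_len(n) - 1) * rec$fs / n
    at50 <- mean(sp[f >= 49.5 & f <= 50.5])
    nearby <- stats::median(sp[(f >= 42 & f <= 47) | (f >= 53 & f <= 58)])
    10 * log10(at50 / nearby)
  }
  quiet <- synthesize_ecog(par, list(electrode_profile("E", "A", "motor")), seed = 42)
  noisy <- synthesize_ecog(par, list(
    electrode_profile("E", "A", "motor", line_noise_amp = 20)), seed = 42)
  expect_lt(abs(peak_db(quiet)), 2)
  expect_gt(peak_db(noisy), 10)
})

test_that("overlapping trials are rejected", {
  par <- make_paradigm(paradigm_config(n_trials_per_mode = 2), seed = 5,
                       modes = "performed")
  par$trials$trial_start[2] <- par$trials$trial_start[2] - 5
  par$trials$trial_end[1] <- par$trials$trial_end[1] + 0.5
  expect_error(
    synthesize_ecog(par, list(electrode_profile("E", "A", "other")), seed = 1),
    "overlap"
  )
})

test_that("electrode profile validation", {
  bad <- matrix(0, 7, 3); bad[2, 1] <- -1
  expect_error(electrode_profile("E", "A", modulation = bad), "> -1")
  expect_error(electrode_profile("E", "A", modulation = matrix(0, 6, 3)), "7 x 3")
  p <- electrode_profile("E", "A", "motor")
  expect_true(all(diff(p$baseline_amp) < 0)) # 1/f: lower bands larger
})
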