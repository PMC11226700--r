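# Frames at 10 Hz over simple hand-built trials keep these tests exact.

mk_frames <- function(trial_spans, dt = 0.1) {
  rows <- lapply(seq_along(trial_spans), function(i) {
    s <- trial_spans[[i]]
    data.frame(trial = i, time = round(seq(s[1], s[2], by = dt), 9))
  })
  df <- do.call(rbind, rows)
  frame_dataset(matrix(0, nrow(df), 3), df$trial, df$time, fs = 1 / dt)
}

test_that("window labels are boundary-inclusive", {
  fr <- mk_frames(list(c(0, 4)))
  win <- data.frame(trial = 1, onset = 1.0, offset = 2.5)
  out <- frames_to_labels(fr, win)
  lab_at <- function(t) out$label[which.min(abs(out$time - t))]
  expect_equal(lab_at(1.0), 1)   # exactly at onset
  expect_equal(lab_at(2.5), 1)   # exactly at offset
  expect_equal(lab_at(2.6), -1)
  expect_equal(lab_at(0.9), -1)
})

test_that("missing windows raise an error that points to the surrogate path", {
  fr <- mk_frames(list(c(0, 2), c(3, 5)))
  win <- data.frame(trial = 1, onset = 0.5, offset = 1.5)
  expect_error(frames_to_labels(fr, win), "surrogate_imagined_timing")
  expect_error(
    frames_to_labels(fr, data.frame(trial = 1:2, onset = c(1, 4), offset = c(0.5, 4.5))),
    "onset < offset"
  )
})

test_that("balancing splits silence evenly, preferring 'before' when short", {
  # trial on [0, 10], 8 speech frames at 4.0..4.7, ample silence both sides
  fr <- mk_frames(list(c(0, 10)))
  fr <- frames_to_labels(fr, data.frame(trial = 1, onset = 4.0, offset = 4.7))
  expect_equal(sum(fr$label == 1), 8)
  sel <- balance_trial(fr, 1)
  lab <- fr$label[sel]
  expect_equal(sum(lab == 1), 8)
  expect_equal(sum(lab == -1), 8)
  tms <- fr$time[sel][lab == -1]
  expect_equal(sum(tms < 4.0), 4)
  expect_equal(sum(tms > 4.7), 4)
  # silence is contiguous and adjacent to the window
  expect_equal(sort(tms[tms < 4]), seq(3.6, 3.9, by = 0.1), tolerance = 1e-9)
  expect_equal(sort(tms[tms > 4.7]), seq(4.8, 5.1, by = 0.1), tolerance = 1e-9)

  # only 2 frames available after the window before the next trial
  sel2 <- balance_trial(fr, 1, next_trial_start = 5.0)
  lab2 <- fr$label[sel2]
  tms2 <- fr$time[sel2][lab2 == -1]
  expect_equal(sum(lab2 == -1), 8)
  expect_equal(sum(tms2 > 4.7), 2) # 4.8, 4.9 only
  expect_equal(sum(tms2 < 4.0), 6) # deficit moved before the window
})

test_that("balancing degenerate cases", {
  fr <- mk_frames(list(c(0, 3)))
  fr$label <- rep(-1, length(fr$label))
  expect_warning(sel <- balance_trial(fr, 1), "no speech frames")
  expect_length(sel, 0)
  # insufficient silence in total
  fr2 <- mk_frames(list(c(0, 1)))
  fr2 <- frames_to_labels(fr2, data.frame(trial = 1, onset = 0.1, offset = 0.9))
  expect_error(balance_trial(fr2, 1), "silence frames")
  # odd speech count: extra frame goes before the window
  fr3 <- mk_frames(list(c(0, 10)))
  fr3 <- frames_to_labels(fr3, data.frame(trial = 1, onset = 4.0, offset = 4.6))
  sel3 <- balance_trial(fr3, 1)
  tms3 <- fr3$time[sel3][fr3$label[sel3] == -1]
  expect_equal(sum(tms3 < 4.0), 4)
  expect_equal(sum(tms3 > 4.6), 3)
})

test_that("balance_dataset enforces exact global and per-trial balance", {
  set.seed(11)
  for (rep in 1:5) {
    spans <- list(c(0, 8), c(9, 18), c(19, 30))
    fr <- mk_frames(spans)
    wins <- data.frame(
      trial = 1:3,
      onset = c(2, 11, 22) + runif(3, -0.5, 0.5),
      offset = c(5, 14, 26) + runif(3, -0.5, 0.5)
    )
    trials <- data.frame(trial = 1:3, trial_start = sapply(spans, `[`, 1))
    bal <- balance_dataset(frames_to_labels(fr, wins), trials)
    expect_equal(sum(bal$label == 1), sum(bal$label == -1))
    for (tr in 1:3) {
      l <- bal$label[bal$trial == tr]
      expect_equal(sum(l == 1), sum(l == -1))
    }
  }
})

test_that("surrogate timing reproduces the hand-worked consensus example", {
  # 10 trials, per-frame speech counts [0,0,2,9,10,10,9,1,0]; go cue before
  # frame 3 (1-based). Expected: speech {5,6}; silence {1,2} and {9};
  # discarded {3,4,7,8}.
  counts <- c(0, 0, 2, 9, 10, 10, 9, 1, 0)
  L <- sapply(counts, function(k) c(rep(1, k), rep(0, 10 - k)))
  st <- surrogate_imagined_timing(L, go_cue_frame = 3, fs = 10, end_max = 0.5)
  expect_equal(st$speech, 5:6)
  expect_equal(st$silence_pre, 1:2)
  expect_equal(st$silence_end, 9)
  expect_equal(st$discarded, c(3, 4, 7, 8))
})

test_that("surrogate thresholds are strict and consensus is required", {
  # 9 of 10 positive -> average 0.9, NOT speech
  L <- rbind(matrix(1, 9, 3), 0)
  expect_error(surrogate_imagined_timing(L, 1, fs = 10),
               "no consensus")
  # identical trials: surrogate window equals the common window
  one <- c(0, 0, 1, 1, 1, 0, 0)
  L2 <- matrix(rep(one, 8), nrow = 8, byrow = TRUE)
  st <- surrogate_imagined_timing(L2, go_cue_frame = 2, fs = 10)
  expect_equal(st$speech, 3:5)
  expect_error(surrogate_imagined_timing(L2[1, , drop = FALSE], 2, fs = 10),
               "at least 2")
})

test_that("surrogate implementation matches a brute-force rule evaluator", {
  # independent frame-by-frame evaluator of the 0.9/0.1/500 ms rules
  brute <- function(L, go, fs, end_max = 0.5) {
    avg <- colMeans(L)
    nf <- length(avg)
    # longest contiguous run with avg > 0.9, first on ties
    best <- NULL; best_len <- 0; i <- 1
    while (i <= nf) {
      if (avg[i] > 0.9) {
        j <- i
        while (j < nf && avg[j + 1] > 0.9) j <- j + 1
        if (j - i + 1 > best_len) {
          best <- c(i, j); best_len <- j - i + 1
        }
        i <- j + 1
      } else i <- i + 1
    }
    if (is.null(best)) return(NULL)
    speech <- best[1]:best[2]
    sil_pre <- integer(0)
    for (i in seq_len(go - 1)) if (avg[i] < 0.1) sil_pre <- c(sil_pre, i)
    cap <- round(end_max * fs)
    sil_end <- integer(0)
    i <- nf
    while (i > max(speech) && avg[i] < 0.1 && length(sil_end) < cap) {
      sil_end <- c(i, sil_end); i <- i - 1
    }
    list(speech = speech, silence_pre = sil_pre, silence_end = sil_end)
  }
  set.seed(99)
  n_ok <- 0
  for (case in 1:200) {
    nt <- sample(5:12, 1)
    nf <- sample(15:40, 1)
    go <- sample(3:8, 1)
    on <- pmax(go, round(stats::rnorm(nt, go + 3, 1)))
    off <- pmin(nf, on + sample(3:12, nt, replace = TRUE))
    L <- t(sapply(seq_len(nt), function(i) {
      as.numeric(seq_len(nf) >= on[i] & seq_len(nf) <= off[i])
    }))
    ref <- brute(L, go, fs = 10)
    if (is.null(ref)) {
      expect_error(surrogate_imagined_timing(L, go, fs = 10), "no consensus")
    } else {
      st <- surrogate_imagined_timing(L, go, fs = 10)
      expect_equal(st$speech, ref$speech)
      expect_equal(st$silence_pre, ref$silence_pre)
      expect_equal(st$silence_end, ref$silence_end)
      n_ok <- n_ok + 1
    }
  }
  expect_gt(n_ok, 50) # the generator produces plenty of consensus cases
})

test_that("surrogate window is conservative w.r.t. the performed trials", {
  set.seed(123)
  for (rep in 1:20) {
    nt <- 10; nf <- 50; go <- 10
    on <- go + sample(3:8, nt, replace = TRUE)
    off <- on + sample(10:25, nt, replace = TRUE)
    off <- pmin(off, nf - 2)
    L <- t(sapply(seq_len(nt), function(i) {
      as.numeric(seq_len(nf) >= on[i] & seq_len(nf) <= off[i])
    }))
    st <- tryCatch(surrogate_imagined_timing(L, go, fs = 10),
                   error = function(e) NULL)
    if (is.null(st)) next
    expect_gte(min(st$speech), min(on)) # onset overestimated
    expect_lte(max(st$speech), max(off)) # offset underestimated
  }
})

test_that("passive dataset takes the cue-centered window with silence labels", {
  fr <- mk_frames(list(c(0, 20)), dt = 1 / 256)
  cue <- data.frame(trial = 1, cue_onset = 10)
  pas <- passive_dataset(fr, cue, width = 4)
  expect_equal(nrow(pas$X), 4 * 256) # 1024 frames
  expect_true(all(pas$label == -1))
  expect_true(all(pas$time >= 8 & pas$time < 12))
  expect_equal(nrow(passive_dataset(fr, cue, width = 0)$X), 0)
})

test_that("passive exclusion rule uses a strict 50% cutoff", {
  expect_equal(apply_passive_exclusion(74, 45), list(score = 50, excluded = TRUE))
  expect_equal(apply_passive_exclusion(74, 50), list(score = 74, excluded = FALSE))
  expect_equal(apply_passive_exclusion(50, 90), list(score = 50, excluded = FALSE))
  expect_error(apply_passive_exclusion(120, 50))
})
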