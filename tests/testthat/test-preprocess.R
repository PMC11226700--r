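fs <- 256

test_that("artifact screening masks channels that ever exceed the limit", {
  set.seed(1)
  sig <- matrix(rnorm(3 * fs * 2, sd = 100), nrow = 3)
  sig[2, 100] <- 1200 # one 1.2 mV sample
  rec <- ecog_recording(sig, fs, data.frame(
    channel = c("a", "b", "c"), grid = "G", region = "other"))
  expect_equal(screen_artifacts(rec), c(a = TRUE, b = FALSE, c = TRUE))
  # all channels within 0.3 mV: everything retained
  rec2 <- ecog_recording(pmin(pmax(sig[-2, , drop = FALSE], -300), 300), fs,
                         data.frame(channel = c("a", "c"), grid = "G"))
  expect_true(all(screen_artifacts(rec2)))
  # degenerate empty recording: empty mask, no failure
  rec0 <- ecog_recording(matrix(numeric(0), nrow = 0), fs,
                         data.frame(channel = character(0), grid = character(0)))
  expect_length(screen_artifacts(rec0), 0)
})

test_that("common average reference subtracts the per-grid mean", {
  sig <- matrix(rep(c(1, 2, 3, 4), each = 10), nrow = 4, byrow = FALSE)
  sig <- matrix(c(1, 2, 3, 4), nrow = 4, ncol = 10)
  rec <- ecog_recording(sig, fs, data.frame(
    channel = letters[1:4], grid = "G"))
  out <- common_average_reference(rec)
  expect_equal(out$signals[, 1], c(a = -1.5, b = -0.5, c = 0.5, d = 1.5))
  # within-grid mean is zero at every sample
  expect_equal(max(abs(colMeans(out$signals))), 0, tolerance = 1e-12)
})

test_that("CAR edge cases: single-channel grid zeroes; symmetric pair unchanged", {
  set.seed(2)
  x <- rnorm(100)
  rec1 <- ecog_recording(matrix(x, nrow = 1), fs,
                         data.frame(channel = "solo", grid = "G"))
  expect_equal(unname(common_average_reference(rec1)$signals[1, ]), rep(0, 100))
  rec2 <- ecog_recording(rbind(x, -x), fs,
                         data.frame(channel = c("p", "m"), grid = "G"))
  out2 <- common_average_reference(rec2)
  expect_equal(unname(out2$signals[1, ]), x)
  # grids are referenced independently
  rec3 <- ecog_recording(rbind(x + 5, x - 5, rnorm(100)), fs, data.frame(
    channel = c("a", "b", "c"), grid = c("G1", "G1", "G2")))
  out3 <- common_average_reference(rec3)
  expect_equal(unname(out3$signals[1, ]), rep(5, 100))
  expect_equal(max(abs(out3$signals[3, ])), 0, tolerance = 1e-12)
})

test_that("line-noise notch: 50 Hz crushed, 10 Hz and DC intact", {
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  interior <- seq(5 * fs, 15 * fs)
  rms <- function(v) sqrt(mean(v^2))
  mkrec <- function(x) signal_recording(x, fs)
  y50 <- notch_line_noise(mkrec(sin(2 * pi * 50 * t)))$signals[1, ]
  expect_lt(rms(y50[interior]), 0.1 * sqrt(0.5))
  y10 <- notch_line_noise(mkrec(sin(2 * pi * 10 * t)))$signals[1, ]
  expect_equal(rms(y10[interior]), sqrt(0.5), tolerance = 0.01)
  ydc <- notch_line_noise(mkrec(rep(3, length(t))))$signals[1, ]
  expect_equal(max(abs(ydc - 3)), 0, tolerance = 1e-6)
  expect_error(notch_line_noise(mkrec(t), line_freq = 140), "Nyquist")
})

test_that("envelope extraction: tone lands in its band with a steady envelope", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rec <- signal_recording(sin(2 * pi * 10 * t), fs)
  env <- extract_envelopes(rec)
  interior <- seq(20 * fs, 40 * fs)
  alpha <- env$values[1, match("alpha", env$bands$band), ]
  delta <- env$values[1, match("delta", env$bands$band), ]
  expect_equal(mean(alpha[interior]), 1, tolerance = 0.05)
  expect_lt(max(delta[interior]), 0.05)
})

test_that("amplitude step transitions at the smoother's seconds-scale pace", {
  t <- seq(0, 80 - 1 / fs, by = 1 / fs)
  n <- length(t)
  amp <- c(rep(1, n / 2), rep(2, n / 2))
  rec <- signal_recording(amp * sin(2 * pi * 50 * t), fs)
  env <- extract_envelopes(rec)
  lg <- env$values[1, match("lowgamma", env$bands$band), ]
  expect_equal(mean(lg[seq(20 * fs, 35 * fs)]), 1, tolerance = 0.05)
  expect_equal(mean(lg[seq(55 * fs, 70 * fs)]), 2, tolerance = 0.05)
  # oracle: the transition should match the 0.25 Hz low-pass step response
  f <- butter_sos(4, 0.25, fs, "low")
  oracle <- filtfilt_sos(f, amp)
  win <- seq(n / 2 - 6 * fs, n / 2 + 6 * fs)
  expect_lt(max(abs(lg[win] - oracle[win])), 0.1)
})

test_that("pipeline is linear in raw signal amplitude", {
  set.seed(3)
  x <- rnorm(30 * fs)
  e1 <- extract_envelopes(signal_recording(x, fs))
  ek <- extract_envelopes(signal_recording(4 * x, fs))
  expect_equal(ek$values, 4 * e1$values, tolerance = 1e-6)
})

test_that("feature construction: column counts, order and edge handling", {
  sp <- small_pipeline()
  tr <- sp$paradigm$trials[sp$paradigm$trials$mode == "performed", ]
  fr <- trial_frames(tr, sp$env$fs, stride = 16)
  full <- build_features(sp$env, "M1", fr, "full")
  expect_equal(ncol(full$X), 21)
  expect_equal(colnames(full$X)[1:4],
               c("delta.m125", "delta.c0", "delta.p125", "theta.m125"))
  low <- build_features(sp$env, "M1", fr, "low")
  expect_equal(ncol(low$X), 15)
  expect_false(any(grepl("gamma", colnames(low$X))))
  gam <- build_features(sp$env, "M1", fr, "gamma")
  expect_equal(ncol(gam$X), 6)
  expect_equal(colnames(gam$X)[1], "lowgamma.m125")
  expect_error(build_features(sp$env, "XX", fr), "unknown channel")
  # frames hugging the record edge are dropped, with a message
  edge <- data.frame(trial = 1, time = c(0, 0.05, 10))
  expect_message(out <- build_features(sp$env, "M1", edge),
                 "dropped 2 frame")
  expect_equal(nrow(out$X), 1)
})

test_that("constant envelopes give identical lag columns", {
  vals <- array(rep(1:7, each = 1), dim = c(1, 7, 1000))
  for (b in 1:7) vals[1, b, ] <- b
  env <- structure(list(values = vals, fs = fs, bands = band_set(fs),
                        channels = data.frame(channel = "c", grid = "g")),
                   class = "envelope_tensor")
  fr <- data.frame(trial = 1, time = seq(0.5, 3, by = 0.1))
  ds <- build_features(env, 1, fr)
  for (b in seq_len(7)) {
    block <- ds$X[, (3 * b - 2):(3 * b)]
    expect_equal(block[, 1], block[, 2])
    expect_equal(block[, 2], block[, 3])
    expect_equal(block[1, 1], b, ignore_attr = TRUE)
  }
})

test_that("z-scoring uses training statistics only and handles degeneracy", {
  set.seed(4)
  tr <- frame_dataset(matrix(rnorm(600, 2, 2), 200, 3), rep(1:4, each = 50),
                      seq_len(200) / 256)
  z <- zscore_features(tr)
  expect_equal(unname(colMeans(z$X)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(z$X, 2, sd)), rep(1, 3), tolerance = 1e-10)
  # train mean 2, sd 2 (column 0,2,4), value 4 -> exactly 1
  tr2 <- frame_dataset(matrix(c(0, 2, 4), 3, 1), rep(1, 3), 1:3 / 256)
  ap <- zscore_features(tr2, frame_dataset(matrix(4), 1, 0.1))
  expect_equal(ap$X[1, 1], 1)
  # statistics come from train only
  manual <- (4 - colMeans(tr$X)) / apply(tr$X, 2, sd)
  ap2 <- zscore_features(tr, frame_dataset(matrix(4, 1, 3), 1, 0.1))
  expect_equal(unname(ap2$X[1, ]), unname(manual))
  # constant column: centered to zero, no division error
  trc <- frame_dataset(cbind(rnorm(100), 7), rep(1:2, each = 50), 1:100 / 256)
  zc <- zscore_features(trc)
  expect_equal(unname(zc$X[, 2]), rep(0, 100))
})
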