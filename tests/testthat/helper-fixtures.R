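# Shared fixtures, all generated in code.

# Gaussian frame dataset with a known linear signal: feature columns
# carry d * label on `informative` columns plus unit noise. Cheap stand-in
# for envelope features when a test targets the detector/ensemble/stats
# machinery rather than the DSP chain.
quick_frames <- function(n_trials = 10, frames_per_trial = 40, d = 1,
                         p = 21, informative = 1, seed = 1,
                         band_subset = "full") {
  set.seed(seed)
  n <- n_trials * frames_per_trial
  half <- frames_per_trial / 2
  label <- rep(rep(c(1, -1), each = half), n_trials)
  X <- matrix(rnorm(n * p), n, p)
  for (j in informative) X[, j] <- X[, j] + d * label
  nb <- p / 3
  bn <- if (nb == 7) band_set()$band else paste0("band", seq_len(nb))
  colnames(X) <- as.vector(t(outer(bn, c("m125", "c0", "p125"), paste, sep = ".")))
  frame_dataset(
    X,
    trial = rep(seq_len(n_trials), each = frames_per_trial),
    time = seq_len(n) / 256,
    label = label, fs = 256, band_subset = band_subset
  )
}

# One small synthetic recording + envelopes, cached per test run.
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pc <- paradigm_config(n_trials_per_mode = 6)
      par <- make_paradigm(pc, seed = 42)
      profs <- list(
        electrode_profile("M1", "A", "motor"),
        electrode_profile("O1", "B", "other")
      )
      rec <- synthesize_ecog(par, profs, seed = 43)
      env <- extract_envelopes(rec)
      cache <<- list(paradigm = par, rec = rec, env = env)
    }
    cache
  }
})

# single-channel recording wrapper around a plain signal vector
signal_recording <- function(x, fs = 256, region = "other") {
  ecog_recording(matrix(x, nrow = 1), fs,
                 data.frame(channel = "C1", grid = "G1", region = region))
}
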