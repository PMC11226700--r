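#' Canonical seven-band ECoG filter bank
#'
#' The frequency bands used throughout the pipeline: delta (0.5-4 Hz),
#' theta (4-8), alpha (8-12), beta1 (12-24), beta2 (24-40), low-gamma
#' (40-70) and high-gamma (70-120). The high-gamma upper edge must stay
#' below the Nyquist frequency, which it does at the standard 256 Hz
#' sampling rate.
#'
#' @param fs sampling rate in Hz, used only to validate the Nyquist bound.
#' @return a data.frame with columns `band`, `low`, `high` (Hz), class
#'   `band_set`.
#' @export
band_set <- function(fs = 256) {
  bands <- data.frame(
    band = c("delta", "theta", "alpha", "beta1", "beta2", "lowgamma", "highgamma"),
    low  = c(0.5, 4, 8, 12, 24, 40, 70),
    high = c(4, 8, 12, 24, 40, 70, 120),
    stringsAsFactors = FALSE
  )
  if (max(bands$high) >= fs / 2) {
    stop(sprintf(
      "band_set: high-gamma edge %g Hz is not below Nyquist (%g Hz)",
      max(bands$high), fs / 2
    ))
  }
  class(bands) <- c("band_set", "data.frame")
  bands
}

#' Resolve a band-subset tag to band names
#'
#' @param subset one of `"full"` (all 7 bands), `"low"` (delta through
#'   beta2) or `"gamma"` (low- and high-gamma).
#' @return character vector of band names.
#' @export
band_subset_names <- function(subset = c("full", "low", "gamma")) {
  subset <- match.arg(subset)
  all <- band_set()$band
  switch(subset,
    full  = all,
    low   = all[1:5],
    gamma = all[6:7]
  )
}

#' Feature lags used by the frame detector
#'
#' The detector looks at each band's smoothed envelope at the frame time
#' and at -125 ms and +125 ms around it.
#' @return numeric vector of lags in seconds, ordered as the feature
#'   columns are (lag-minor within each band).
#' @export
feature_lags <- function() c(-0.125, 0, 0.125)

# Column names for a feature matrix: band-major, lag-minor.
feature_colnames <- function(bands) {
  lagtag <- c("m125", "c0", "p125")
  as.vector(t(outer(bands, lagtag, paste, sep = ".")))
}
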