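# Single-electrode frame-wise detector: linear regression onto +/-1 labels
# thresholded at zero, evaluated with leave-one-trial-out cross-validation,
# interpreted through Haufe activation patterns.

#' Fit the linear frame detector
#'
#' Ordinary least squares of the +/-1 labels on the (z-scored) features,
#' with intercept. An optional ridge penalty exists but defaults off: with
#' 21 features and thousands of frames the problem is well posed and the
#' method calls for plain linear regression.
#'
#' @param X numeric feature matrix (frames x features), z-scored.
#' @param y labels in {-1, +1}.
#' @param band_subset tag stored on the model.
#' @param ridge ridge penalty (0 = OLS).
#' @return list of class `detector_model`: `weights`, `intercept`,
#'   `band_subset`.
#' @export
fit_detector <- function(X, y, band_subset = "full", ridge = 0) {
  X <- as.matrix(X)
  if (length(unique(sign(y))) < 2) {
    stop("fit_detector: both classes must be present in y")
  }
  Z <- cbind(1, X)
  if (ridge > 0) {
    A <- crossprod(Z) + diag(c(0, rep(ridge, ncol(X))))
    beta <- solve(A, crossprod(Z, y))
  } else {
    beta <- stats::.lm.fit(Z, y)$coefficients
  }
  structure(
    list(weights = as.numeric(beta[-1]), intercept = as.numeric(beta[1]),
         band_subset = band_subset, feature_names = colnames(X)),
    class = "detector_model"
  )
}

#' Predict frame labels with a detector model
#'
#' The continuous regression output is thresholded at 0: negative means
#' silence (-1); zero or positive means speech (+1).
#'
#' @param model a `detector_model`.
#' @param X feature matrix with the same columns the model was fitted on.
#' @return list with `continuous` and `decision` vectors.
#' @export
predict_frames <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights)) {
    stop(sprintf("predict_frames: %d features but model has %d weights",
                 ncol(X), length(model$weights)))
  }
  cont <- as.numeric(X %*% model$weights + model$intercept)
  list(continuous = cont, decision = ifelse(cont >= 0, 1, -1))
}

#' Haufe activation pattern of a linear detector
#'
#' Converts the backward (decoding) weights into forward-model activation
#' coefficients: `a = Cov(X) w / Var(w'X + b)`, the single-latent case of
#' Haufe's transformation. Returned reshaped as a bands x lags matrix
#' (band-major rows, lags -125/0/+125 ms in columns).
#'
#' @param model a `detector_model`.
#' @param X the (z-scored) training feature matrix the model was fitted on.
#' @return numeric bands x 3 matrix (un-normalized).
#' @export
activation_pattern <- function(model, X) {
  X <- as.matrix(X)
  w <- model$weights
  yhat <- as.numeric(X %*% w)
  v <- stats::var(yhat)
  a <- if (v > 0) as.numeric(stats::cov(X) %*% w) / v else {
    warning("activation_pattern: zero-variance model output; returning zeros")
    rep(0, length(w))
  }
  if (length(w) %% 3 != 0) { # no band x lag structure (e.g. stacked models)
    return(matrix(a, nrow = 1))
  }
  pat <- matrix(a, ncol = 3, byrow = TRUE)
  nb <- length(w) / 3
  bands <- if (!is.null(colnames(X))) {
    unique(sub("\\.(m125|c0|p125)$", "", colnames(X)))
  } else {
    paste0("band", seq_len(nb))
  }
  dimnames(pat) <- list(bands, c("m125", "c0", "p125"))
  pat
}

#' Normalize an activation pattern to unit maximum magnitude
#' @param pattern numeric matrix.
#' @return pattern scaled so that `max(abs(pattern)) == 1` (zeros stay zero).
#' @export
normalize_pattern <- function(pattern) {
  m <- max(abs(pattern))
  if (m > 0) pattern / m else pattern
}

#' Gamma activation of a full-band pattern
#'
#' The mean of the six activation coefficients in the low-gamma and
#' high-gamma rows (all three lags), summarizing how strongly the gamma
#' bands drive the detector.
#'
#' @param pattern bands x lags activation matrix with band rownames.
#' @return scalar.
#' @export
gamma_activation <- function(pattern) {
  rows <- c("lowgamma", "highgamma")
  if (!all(rows %in% rownames(pattern))) {
    stop("gamma_activation: pattern lacks gamma-band rows (band subset model?)")
  }
  mean(pattern[rows, ])
}

#' Leave-one-trial-out cross-validation of the single-electrode detector
#'
#' One fold per trial: features are z-scored with training-fold statistics
#' only, the detector is fitted on the training folds and scored on every
#' frame of the held-out trial. Reports the per-trial accuracy (percent of
#' frames correct), their unweighted mean, the per-frame continuous
#' outputs, and the fold-averaged, max-normalized activation pattern.
#'
#' @param frames a labeled (`+1`/`-1`) `frame_dataset`.
#' @param ridge ridge penalty passed to [fit_detector()].
#' @param patterns set `FALSE` to skip activation-pattern computation.
#' @return list of class `cv_result`: `trial`, `trial_acc` (percent),
#'   `mean_acc`, `continuous` (per frame, in input order), `decision`,
#'   `pattern` (normalized), `n_folds`.
#' @export
loto_cv <- function(frames, ridge = 0, patterns = TRUE) {
  lab <- frames$label
  keep_tr <- vapply(split(seq_along(lab), frames$trial),
                    function(i) !all(is.na(lab[i])), TRUE)
  ids <- sort(unique(frames$trial))[keep_tr]
  if (length(ids) < length(unique(frames$trial))) {
    message("loto_cv: skipped trial(s) without labeled frames")
  }
  if (length(ids) < 3) stop("loto_cv: need at least 3 trials with labels")
  use <- which(frames$trial %in% ids & !is.na(lab))
  fr <- subset_frames(frames, use)

  acc <- numeric(length(ids))
  cont <- numeric(nrow(fr$X))
  pat_sum <- NULL
  for (k in seq_along(ids)) {
    te <- which(fr$trial == ids[k])
    tr <- which(fr$trial != ids[k])
    train <- subset_frames(fr, tr)
    trz <- zscore_features(train)
    tez <- zscore_features(train, subset_frames(fr, te))
    model <- fit_detector(trz$X, trz$label, fr$band_subset, ridge)
    pred <- predict_frames(model, tez$X)
    cont[te] <- pred$continuous
    acc[k] <- 100 * mean(pred$decision == fr$label[te])
    if (patterns) {
      p <- activation_pattern(model, trz$X)
      pat_sum <- if (is.null(pat_sum)) p else pat_sum + p
    }
  }
  pattern <- if (patterns) normalize_pattern(pat_sum / length(ids)) else NULL
  structure(
    list(trial = ids, trial_acc = acc, mean_acc = mean(acc),
         continuous = cont, decision = ifelse(cont >= 0, 1, -1),
         label = fr$label, frame_trial = fr$trial,
         pattern = pattern, n_folds = length(ids)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean accuracy %.2f%% (trial range %.1f-%.1f%%)\n",
              x$n_folds, x$mean_acc, min(x$trial_acc), max(x$trial_acc)))
  invisible(x)
}
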