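# Multi-electrode model: correlation-based electrode ranking, stacking of
# single-electrode continuous outputs into a second-level regressor, and
# recursive selection of the optimal electrode count.

#' Rank electrodes by band-averaged feature-label correlation
#'
#' For each electrode the Pearson correlation between every feature column
#' and the labels is computed (constant columns count as 0), the 3 lag
#' correlations of each band are averaged, and the electrode's score is the
#' maximum absolute band average. Electrodes are returned in descending
#' score order, ties broken by electrode index. Call this on training-fold
#' rows only — the ranking is part of the model.
#'
#' @param X_list list of feature matrices (one per electrode, same rows).
#' @param y +/-1 labels.
#' @return list with `order` (electrode indices, best first) and `score`.
#' @export
rank_electrodes <- function(X_list, y) {
  if (length(X_list) < 2) stop("rank_electrodes: need at least 2 electrodes")
  score <- vapply(X_list, function(X) {
    r <- suppressWarnings(stats::cor(X, y))
    r[!is.finite(r)] <- 0
    nb <- nrow(r) / 3
    band_avg <- rowMeans(matrix(r, nrow = nb, byrow = TRUE))
    max(abs(band_avg))
  }, 0)
  ord <- order(-score, seq_along(score))
  list(order = ord, score = score)
}

#' Fit the second-level (stacked) regressor
#'
#' Linear regression of the labels on the continuous outputs of k
#' first-level electrode models, thresholded at 0 exactly like the
#' single-electrode case.
#'
#' @param outputs frames x k matrix of first-level continuous outputs.
#' @param y +/-1 labels.
#' @return a `detector_model` over the k outputs.
#' @export
fit_stacked <- function(outputs, y) {
  outputs <- as.matrix(outputs)
  if (ncol(outputs) == 0) stop("fit_stacked: need at least one first-level output")
  fit_detector(outputs, y, band_subset = "stacked")
}

#' Leave-one-trial-out evaluation of stacked multi-electrode models
#'
#' For every fold the electrodes are re-ranked on the training folds only,
#' per-electrode detectors are fitted, and stacked models for k = 1..K
#' electrodes are evaluated on the held-out trial. Reports the per-trial
#' accuracies for every k.
#'
#' @param frames_list list of labeled `frame_dataset`s, one per electrode,
#'   with identical trials, times and labels.
#' @param K maximal number of electrodes to stack.
#' @return list of class `ensemble_cv`: `per_k` (list of `cv_result`-like
#'   lists), `K`.
#' @export
ensemble_cv <- function(frames_list, K = length(frames_list)) {
  E <- length(frames_list)
  stopifnot(E >= 1, K >= 1, K <= E)
  f1 <- frames_list[[1]]
  for (f in frames_list[-1]) {
    stopifnot(identical(f$trial, f1$trial), identical(f$label, f1$label))
  }
  use <- which(!is.na(f1$label))
  frames_list <- lapply(frames_list, subset_frames, i = use)
  f1 <- frames_list[[1]]
  ids <- sort(unique(f1$trial))
  if (length(ids) < 3) stop("ensemble_cv: need at least 3 trials")

  acc <- matrix(0, length(ids), K)
  for (fold in seq_along(ids)) {
    te <- which(f1$trial == ids[fold])
    tr <- which(f1$trial != ids[fold])
    ytr <- f1$label[tr]
    Xtr_z <- vector("list", E)
    out_tr <- matrix(0, length(tr), E)
    out_te <- matrix(0, length(te), E)
    for (e in seq_len(E)) {
      train <- subset_frames(frames_list[[e]], tr)
      trz <- zscore_features(train)
      tez <- zscore_features(train, subset_frames(frames_list[[e]], te))
      m <- fit_detector(trz$X, ytr, f1$band_subset)
      out_tr[, e] <- predict_frames(m, trz$X)$continuous
      out_te[, e] <- predict_frames(m, tez$X)$continuous
      Xtr_z[[e]] <- trz$X
    }
    ord <- rank_electrodes(Xtr_z, ytr)$order
    yte <- f1$label[te]
    for (k in seq_len(K)) {
      sel <- ord[seq_len(k)]
      sm <- fit_stacked(out_tr[, sel, drop = FALSE], ytr)
      dec <- predict_frames(sm, out_te[, sel, drop = FALSE])$decision
      acc[fold, k] <- 100 * mean(dec == yte)
    }
  }
  per_k <- lapply(seq_len(K), function(k) {
    list(trial = ids, trial_acc = acc[, k], mean_acc = mean(acc[, k]), k = k)
  })
  structure(list(per_k = per_k, K = K), class = "ensemble_cv")
}

#' Select the optimal electrode count
#'
#' Recursive rule: the 1-electrode model is the initial incumbent; for
#' k = 2..K the k-electrode model replaces the incumbent if it beats it
#' (one-sided paired Wilcoxon over per-trial accuracies, alpha = 0.05).
#' If no k ever wins, the k with the highest mean accuracy is returned
#' (first under ties).
#'
#' @param cv an `ensemble_cv` (or a list of per-k results with `trial_acc`
#'   and `mean_acc`).
#' @param alpha significance level.
#' @return list with `k_opt`, `mean_acc` (vector over k), `significant`
#'   (whether any k won a test).
#' @export
select_optimal_count <- function(cv, alpha = 0.05) {
  per_k <- if (inherits(cv, "ensemble_cv")) cv$per_k else cv
  K <- length(per_k)
  if (K < 1) stop("select_optimal_count: need at least one model")
  mean_acc <- vapply(per_k, function(r) r$mean_acc, 0)
  incumbent <- 1
  won <- FALSE
  if (K > 1) {
    for (k in 2:K) {
      p <- compare_paired(per_k[[k]]$trial_acc, per_k[[incumbent]]$trial_acc,
                          "greater")$p_value
      if (p < alpha) {
        incumbent <- k
        won <- TRUE
      }
    }
  }
  k_opt <- if (won) incumbent else which.max(mean_acc)
  list(k_opt = k_opt, mean_acc = mean_acc, significant = won)
}
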