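# Transfer: train-on-one / test-on-another evaluation across speech modes
# and subjects, and the pooled multi-subject model.

#' Restrict a full-band frame dataset to a band subset
#'
#' @param frames a `frame_dataset` built with the full band set.
#' @param band_subset `"full"`, `"low"` or `"gamma"`.
#' @return a `frame_dataset` with the subset's columns.
#' @export
restrict_bands <- function(frames, band_subset = c("full", "low", "gamma")) {
  band_subset <- match.arg(band_subset)
  if (band_subset == "full") return(frames)
  cols <- feature_colnames(band_subset_names(band_subset))
  if (!all(cols %in% colnames(frames$X))) {
    stop("restrict_bands: requested bands not present in the feature matrix")
  }
  out <- frames
  out$X <- frames$X[, cols, drop = FALSE]
  out$band_subset <- band_subset
  out
}

#' Transfer a detector between datasets (speech modes or subjects)
#'
#' One model is fitted on *all* frames of the source dataset and evaluated
#' per trial on the target dataset. Each dataset is z-scored with its own
#' full-set statistics — mirroring the offline evaluation protocol, not a
#' deployable causal system. The low-band variant used for temporal-lobe
#' imagined transfers is obtained by passing `band_subset = "low"`.
#'
#' @param source,target labeled `frame_dataset`s with matching feature
#'   construction.
#' @param band_subset optional restriction applied to both sets.
#' @return list with `mean_acc`, `trial`, `trial_acc`, `decision`,
#'   `continuous`, `model`.
#' @export
transfer_evaluate <- function(source, target, band_subset = NULL) {
  if (!is.null(band_subset)) {
    source <- restrict_bands(source, band_subset)
    target <- restrict_bands(target, band_subset)
  }
  if (ncol(source$X) != ncol(target$X)) {
    stop(sprintf("transfer_evaluate: source has %d features, target %d",
                 ncol(source$X), ncol(target$X)))
  }
  src <- subset_frames(source, which(!is.na(source$label)))
  tgt <- subset_frames(target, which(!is.na(target$label)))
  srz <- zscore_features(src)
  tgz <- zscore_features(tgt) # target's own statistics
  model <- fit_detector(srz$X, srz$label, src$band_subset)
  pred <- predict_frames(model, tgz$X)
  ids <- sort(unique(tgt$trial))
  trial_acc <- vapply(ids, function(tr) {
    i <- tgt$trial == tr
    100 * mean(pred$decision[i] == tgt$label[i])
  }, 0)
  list(
    mean_acc = mean(trial_acc), trial = ids, trial_acc = trial_acc,
    decision = pred$decision, continuous = pred$continuous,
    label = tgt$label, frame_trial = tgt$trial, model = model
  )
}

#' Pooled multi-subject cross-validation
#'
#' Trains a single detector on frames pooled over subjects. Trial counts
#' are first equalized by seeded random subsampling of the larger subjects;
#' each subject's features are z-scored with that subject's own full-set
#' statistics before pooling. Cross-validation folds hold out exactly one
#' trial per subject.
#'
#' @param datasets named list of labeled `frame_dataset`s, one per subject.
#' @param seed seed for trial equalization and fold assignment.
#' @return list of class `pooled_cv`: `per_subject` (list with `trial`,
#'   `trial_acc`, `mean_acc`), `mean_acc` (grand mean over subjects),
#'   `n_folds`, `n_trials_used`.
#' @export
fit_pooled <- function(datasets, seed = 1) {
  if (is.null(names(datasets))) names(datasets) <- paste0("S", seq_along(datasets))
  datasets <- lapply(datasets, function(d) subset_frames(d, which(!is.na(d$label))))
  counts <- vapply(datasets, function(d) length(unique(d$trial)), 0L)
  drop <- counts < 2
  if (any(drop)) {
    message("fit_pooled: excluded subject(s) with < 2 trials: ",
            paste(names(datasets)[drop], collapse = ", "))
    datasets <- datasets[!drop]
    counts <- counts[!drop]
  }
  if (length(datasets) < 1) stop("fit_pooled: no usable subjects")
  n_min <- min(counts)
  set.seed(seed)
  folds_of <- vector("list", length(datasets))
  for (s in seq_along(datasets)) {
    ids <- sort(unique(datasets[[s]]$trial))
    keep <- sort(sample(ids, n_min))
    datasets[[s]] <- subset_frames(datasets[[s]],
                                   which(datasets[[s]]$trial %in% keep))
    # fold assignment: one trial per subject per fold, in random order
    folds_of[[s]] <- keep[sample.int(n_min)]
  }
  zs <- lapply(datasets, zscore_features) # per-subject full-set statistics

  per_subject <- lapply(seq_along(datasets), function(s) {
    list(trial = folds_of[[s]], trial_acc = rep(NA_real_, n_min))
  })
  names(per_subject) <- names(datasets)
  for (f in seq_len(n_min)) {
    Xtr <- NULL; ytr <- NULL
    test <- vector("list", length(datasets))
    for (s in seq_along(datasets)) {
      held <- folds_of[[s]][f]
      tr <- which(zs[[s]]$trial != held)
      te <- which(zs[[s]]$trial == held)
      Xtr <- rbind(Xtr, zs[[s]]$X[tr, , drop = FALSE])
      ytr <- c(ytr, zs[[s]]$label[tr])
      test[[s]] <- te
    }
    model <- fit_detector(Xtr, ytr, datasets[[1]]$band_subset)
    for (s in seq_along(datasets)) {
      te <- test[[s]]
      dec <- predict_frames(model, zs[[s]]$X[te, , drop = FALSE])$decision
      per_subject[[s]]$trial_acc[f] <- 100 * mean(dec == zs[[s]]$label[te])
    }
  }
  for (s in seq_along(per_subject)) {
    per_subject[[s]]$mean_acc <- mean(per_subject[[s]]$trial_acc)
  }
  structure(
    list(
      per_subject = per_subject,
      mean_acc = mean(vapply(per_subject, function(x) x$mean_acc, 0)),
      n_folds = n_min, n_trials_used = n_min
    ),
    class = "pooled_cv"
  )
}
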