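# Significance machinery: trial-wise permutation tests against the
# leave-one-trial-out detector, and the paired/unpaired rank tests used for
# model comparisons.

new_permutation_result <- function(observed, null_acc, n_perm, seed,
                                   ge = TRUE) {
  N <- if (ge) sum(null_acc >= observed) else sum(null_acc > observed)
  p <- (N + 1) / (n_perm + 1)
  stopifnot(p > 0, p <= 1)
  structure(
    list(observed = observed, null = null_acc, p_value = p,
         n_perm = n_perm, seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %.2f%%, null mean %.2f%%, p = %.4g (%d permutations)\n",
    x$observed, mean(x$null), x$p_value, x$n_perm
  ))
  invisible(x)
}

# Sample the trial-reversal sign matrix: each column flips the labels of a
# random floor(T/2)-subset of trials (without replacement).
reversal_signs <- function(n_trials, n_perm) {
  half <- n_trials %/% 2
  sg <- matrix(1, n_trials, n_perm)
  for (j in seq_len(n_perm)) {
    sg[sample.int(n_trials, half), j] <- -1
  }
  sg
}

# Vectorized LOTO evaluation over many trial-wise sign flips.
#
# Fitting OLS with an intercept on the raw feature columns yields exactly
# the same predictions as fitting on fold-wise z-scored columns (the fitted
# subspace is identical), so per fold the normal-equations matrix
# A_f = sum_{i != f} Z_i'Z_i is independent of the label signs and can be
# factorized once, while the right-hand side flips sign per reversed trial.
# Returns the per-permutation mean trial accuracy (percent).
loto_null_accuracies <- function(frames, signs) {
  ids <- sort(unique(frames$trial))
  Z <- cbind(1, frames$X)
  p1 <- ncol(Z)
  Ti <- length(ids)
  S <- array(0, dim = c(p1, p1, Ti))
  V <- matrix(0, p1, Ti)
  idx <- vector("list", Ti)
  for (i in seq_len(Ti)) {
    r <- which(frames$trial == ids[i])
    idx[[i]] <- r
    S[, , i] <- crossprod(Z[r, , drop = FALSE])
    V[, i] <- crossprod(Z[r, , drop = FALSE], frames$label[r])
  }
  G <- apply(S, c(1, 2), sum)
  B_full <- V %*% signs # p1 x n_perm, sum of per-trial rhs under each flip
  acc <- matrix(0, Ti, ncol(signs))
  for (f in seq_len(Ti)) {
    A <- G - S[, , f]
    Bf <- B_full - outer(V[, f], signs[f, ])
    coef <- solve(A, Bf)
    P <- Z[idx[[f]], , drop = FALSE] %*% coef # frames x n_perm
    ypos <- frames$label[idx[[f]]] > 0
    base <- colMeans((P >= 0) == ypos)
    acc[f, ] <- ifelse(signs[f, ] == 1, base, 1 - base)
  }
  100 * colMeans(acc)
}

#' Trial-wise permutation test of the cross-validated detector
#'
#' Each replicate reverses all labels of a random half (`floor(T/2)`) of
#' the trials and reruns the full leave-one-trial-out cross-validation;
#' shuffling whole trials rather than individual frames keeps the
#' low-frequency label structure and makes the test conservative. The
#' p-value is `(N + 1) / (n_perm + 1)` with `N` the number of null
#' accuracies at least as large as the observed one (`>=`, the
#' conservative reading; set `strict = TRUE` for `>`).
#'
#' The replicates are evaluated with an algebraically exact fast path
#' (cached per-trial cross-products); 10,000 permutations is the faithful
#' default, reduced values are fine for desk-scale runs.
#'
#' @param frames a labeled, balanced `frame_dataset`.
#' @param n_perm number of permutations.
#' @param seed integer seed for the trial sampling.
#' @param observed optionally, a precomputed [loto_cv()] mean accuracy.
#' @param strict use strict `>` when counting null exceedances.
#' @return a `permutation_result`.
#' @export
permutation_test_cv <- function(frames, n_perm = 10000, seed = 1,
                                observed = NULL, strict = FALSE) {
  use <- which(!is.na(frames$label))
  fr <- subset_frames(frames, use)
  ids <- sort(unique(fr$trial))
  if (length(ids) < 4) stop("permutation_test_cv: need at least 4 trials")
  if (n_perm < 1) stop("permutation_test_cv: n_perm must be >= 1")
  if (is.null(observed)) observed <- loto_cv(fr, patterns = FALSE)$mean_acc
  set.seed(seed)
  signs <- reversal_signs(length(ids), n_perm)
  null_acc <- loto_null_accuracies(fr, signs)
  new_permutation_result(observed, null_acc, n_perm, seed, ge = !strict)
}

#' Permutation test for a transferred (fixed) model
#'
#' For transfer evaluations the trained model stays fixed; only the labels
#' of the validation trials are shuffled. Each replicate reverses the
#' labels of a random half of the target trials and recomputes the mean
#' trial accuracy from the already-made decisions.
#'
#' @param decision per-frame +/-1 decisions of the fixed model on the
#'   target set.
#' @param label per-frame true +/-1 labels.
#' @param trial per-frame trial ids.
#' @param n_perm,seed,strict as in [permutation_test_cv()].
#' @return a `permutation_result`.
#' @export
permutation_test_transfer <- function(decision, label, trial,
                                      n_perm = 10000, seed = 1,
                                      strict = FALSE) {
  ids <- sort(unique(trial))
  per_trial <- vapply(ids, function(tr) {
    i <- trial == tr
    100 * mean(decision[i] == label[i])
  }, 0)
  observed <- mean(per_trial)
  set.seed(seed)
  signs <- reversal_signs(length(ids), n_perm)
  # reversing a trial's labels turns accuracy a into 100 - a
  null_acc <- colMeans(ifelse(signs == 1, per_trial, 100 - per_trial))
  new_permutation_result(observed, null_acc, n_perm, seed, ge = !strict)
}

#' Paired one-sided Wilcoxon signed-rank comparison
#'
#' Compares two paired per-trial accuracy vectors. Zero differences are
#' dropped (standard signed-rank handling); the exact distribution is used
#' for n <= 25 without ties, the normal approximation with continuity
#' correction otherwise. If all differences are zero the comparison is
#' degenerate and p = 1 is returned with a flag.
#'
#' @param a,b paired numeric vectors (e.g. per-trial accuracies).
#' @param alternative `"greater"` tests a > b, `"less"` tests a < b.
#' @return list with `p_value`, `degenerate`.
#' @export
compare_paired <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  d <- a - b
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(p_value = 1, degenerate = TRUE))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  p <- suppressWarnings(stats::wilcox.test(
    nz, alternative = alternative, mu = 0, exact = exact, correct = TRUE
  ))$p.value
  list(p_value = p, degenerate = FALSE)
}

#' Unpaired one-sided Wilcoxon rank-sum comparison
#'
#' @param a,b independent samples.
#' @param alternative `"greater"` tests a stochastically larger than b.
#' @return p-value.
#' @export
compare_unpaired <- function(a, b, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) {
    stop("compare_unpaired: empty sample")
  }
  exact <- length(a) <= 25 && length(b) <= 25 && !any(duplicated(c(a, b)))
  suppressWarnings(stats::wilcox.test(
    a, b, alternative = alternative, exact = exact, correct = TRUE
  ))$p.value
}

#' Bonferroni correction helper
#'
#' Provided for multi-electrode reporting; not applied by default anywhere,
#' matching the per-electrode reporting at a stated alpha.
#'
#' @param p vector of p-values.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p) pmin(1, p * length(p))
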