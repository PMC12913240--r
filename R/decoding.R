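#' Block-average trials to raise SNR before classification
#'
#' Partitions the trials, in temporal order, into `n_blocks` contiguous
#' blocks of `floor(n / n_blocks)` trials (remainder trials at the end are
#' dropped) and averages within each block: 200 trials become 50 blocks of
#' 4. When fewer trials than blocks are available the trials themselves are
#' used as single-trial samples, with a warning.
#'
#' @param ep An `lg_epochs`.
#' @param n_blocks Number of blocks (50 in the published pipeline).
#' @return An `lg_epochs` whose trials are the block averages.
#' @export
block_average <- function(ep, n_blocks = 50) {
  n <- n_trials(ep)
  if (n < n_blocks) {
    warnf("only %d trials for %d blocks; falling back to single-trial samples",
          n, n_blocks)
    return(ep)
  }
  per <- n %/% n_blocks
  used <- n_blocks * per
  out <- array(NA_real_, c(n_blocks, dim(ep$data)[2], dim(ep$data)[3]))
  grp <- rep(seq_len(n_blocks), each = per)
  for (b in seq_len(n_blocks))
    out[b, , ] <- apply(ep$data[which(grp == b), , , drop = FALSE], c(2, 3), mean)
  epoch_set(out, ep$times, ep$channels, baseline_ms = NULL,
            label = ep$label[1], participant_id = ep$participant_id,
            contrast = ep$contrast, ref_labels = ep$ref_labels)
}

#' Restrict epochs to a decoding window
#'
#' Keeps samples with `window_ms[1] <= t < window_ms[2]` (so a 0-300 ms
#' window at 250 Hz keeps exactly 75 samples per channel).
#'
#' @param ep An `lg_epochs`.
#' @param window_ms Length-2 window (ms).
#' @return The cropped `lg_epochs`.
#' @export
crop_to_window <- function(ep, window_ms) {
  keep <- ep$times >= window_ms[1] & ep$times < window_ms[2]
  if (!any(keep)) stopf("decoding window [%g, %g) ms contains no samples",
                        window_ms[1], window_ms[2])
  ep$data <- ep$data[, , keep, drop = FALSE]
  ep$times <- ep$times[keep]
  ep
}

# Flatten an epoch set (non-reference channels x samples) to a samples x
# features matrix.
epochs_features <- function(ep, channels = NULL) {
  ch <- if (is.null(channels)) setdiff(ep$channels, ep$ref_labels)
        else setdiff(channels, ep$ref_labels)
  idx <- match(ch, ep$channels)
  if (anyNA(idx)) stopf("channels missing from epochs: %s",
                        paste(ch[is.na(idx)], collapse = ", "))
  X <- ep$data[, idx, , drop = FALSE]
  dim(X) <- c(dim(X)[1], dim(X)[2] * dim(X)[3])
  X
}

# One cross-validated accuracy: stratified k-fold with freshly shuffled fold
# assignment, per-feature standardization fitted on the training folds only,
# linear SVM (e1071/libsvm) with default regularization.
#
# With many more features than samples the SVM is fit on an exact
# low-dimensional re-coordinatization: a linear SVM depends on the data only
# through inner products, so rows of a Cholesky factor of the (standardized)
# Gram matrix give the identical solution at a fraction of the cost.
cv_accuracy <- function(X, y, k) {
  folds <- integer(length(y))
  for (cl in unique(y))
    folds[y == cl] <- sample_vec(rep_len(seq_len(k), sum(y == cl)))
  yf <- factor(y)
  use_gram <- ncol(X) > nrow(X)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    ntr <- sum(tr)
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- sqrt((colMeans(X[tr, , drop = FALSE]^2) - mu^2) * ntr / (ntr - 1))
    sg[!is.finite(sg) | sg < 1e-12] <- 1
    Xs <- (X - rep(mu, each = nrow(X))) / rep(sg, each = nrow(X))
    if (use_gram) {
      G <- tcrossprod(Xs)
      Z <- t(chol(G + diag(1e-9 * max(diag(G)) + 1e-12, nrow(G))))
      Ztr <- Z[tr, , drop = FALSE]; Zte <- Z[!tr, , drop = FALSE]
    } else {
      Ztr <- Xs[tr, , drop = FALSE]; Zte <- Xs[!tr, , drop = FALSE]
    }
    fit <- e1071::svm(Ztr, yf[tr], kernel = "linear", scale = FALSE,
                      fitted = FALSE, na.action = stats::na.pass)
    accs[f] <- mean(predict(fit, Zte) == yf[!tr])
  }
  mean(accs)
}

#' Individual-level classification sensitivity
#'
#' Quantifies whether one participant's two condition sample sets are
#' discriminable: a linear support-vector machine (default regularization)
#' under stratified fivefold cross-validation, run `n_iter` times with true
#' labels (re-randomized fold assignment each iteration) and `n_iter` times
#' with labels freshly shuffled each iteration (the null). The component is
#' detected when the mean true-label accuracy exceeds the 95th percentile of
#' the null distribution; the empirical p-value (fraction of null accuracies
#' at or above the mean true accuracy) is reported alongside.
#'
#' @param samples_a,samples_b samples x features matrices (e.g. flattened
#'   block averages), one per condition, equal row counts.
#' @param n_iter Iterations per distribution.
#' @param k Cross-validation folds.
#' @param seed Integer seed.
#' @param participant_id,contrast Metadata carried into the result.
#' @return An `lg_sensitivity` object: `true_accuracies`,
#'   `null_accuracies`, `mean_accuracy`, `accuracy_sd`, `threshold`,
#'   `detected`, `p_value`, `n_samples`, `n_features`.
#' @export
evaluate_sensitivity <- function(samples_a, samples_b, n_iter = 1000, k = 5,
                                 seed = NULL, participant_id = NA,
                                 contrast = NA_character_) {
  if (nrow(samples_a) != nrow(samples_b))
    stopf("class imbalance: %d vs %d samples", nrow(samples_a), nrow(samples_b))
  if (nrow(samples_a) < k)
    stopf("need at least k = %d samples per class, got %d", k, nrow(samples_a))
  X <- rbind(samples_a, samples_b)
  y <- rep(c("A", "B"), c(nrow(samples_a), nrow(samples_b)))

  with_seed(seed, {
    true_acc <- vapply(seq_len(n_iter), function(i) cv_accuracy(X, y, k), 0)
    null_acc <- vapply(seq_len(n_iter), function(i)
      cv_accuracy(X, sample_vec(y), k), 0)
    structure(list(
      participant_id = participant_id, contrast = contrast,
      true_accuracies = true_acc, null_accuracies = null_acc,
      mean_accuracy = mean(true_acc), accuracy_sd = sd(true_acc),
      threshold = unname(quantile(null_acc, 0.95)),
      detected = mean(true_acc) > unname(quantile(null_acc, 0.95)),
      p_value = (1 + sum(null_acc >= mean(true_acc))) / (n_iter + 1),
      n_samples = length(y), n_features = ncol(X),
      n_iter = n_iter, k = k), class = "lg_sensitivity")
  })
}

#' @export
print.lg_sensitivity <- function(x, ...) {
  cat(sprintf("<lg_sensitivity> %s participant %s: accuracy %.3f +/- %.3f, null 95th pct %.3f -> %s (p = %.4g)\n",
              x$contrast %||% "", x$participant_id, x$mean_accuracy,
              x$accuracy_sd, x$threshold,
              if (x$detected) "detected" else "not detected", x$p_value))
  invisible(x)
}

#' Sensitivity of a contrast from paired epoch sets
#'
#' Convenience wrapper: block-averages both condition epoch sets, crops them
#' to the contrast's decoding window, flattens channels x time to features
#' and runs [evaluate_sensitivity()].
#'
#' @param A,B Paired `lg_epochs` (e.g. from [extract_epochs()] and
#'   [reject_amplitude()]).
#' @param contrast Contrast spec or name (for the decoding window); defaults
#'   to the one recorded in the epochs.
#' @param n_blocks Blocks for [block_average()].
#' @param channels Optional channel subset (references always excluded).
#' @inheritParams evaluate_sensitivity
#' @return An `lg_sensitivity`.
#' @export
sensitivity_from_epochs <- function(A, B, contrast = NULL, n_blocks = 50,
                                    n_iter = 1000, k = 5, seed = NULL,
                                    channels = NULL) {
  contrast <- contrast %||% A$contrast
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  # The control set is cropped at the same relative sample positions as the
  # test set, so e.g. resting-state epochs (whose own axis ends at 0 ms)
  # contribute the matching stretch of their interval.
  idx <- which(A$times >= contrast$decode_window_ms[1] &
                 A$times < contrast$decode_window_ms[2])
  prep <- function(ep) {
    ep <- block_average(ep, n_blocks)
    ep$data <- ep$data[, , idx, drop = FALSE]
    ep$times <- ep$times[idx]
    epochs_features(ep, channels)
  }
  evaluate_sensitivity(prep(A), prep(B), n_iter = n_iter, k = k, seed = seed,
                       participant_id = A$participant_id,
                       contrast = contrast$name)
}

#' Active-vs-passive sensitivity on global deviant epochs
#'
#' Classifies session condition (active vs passive) from the global-deviant
#' T epochs' decoding window — the individual-level analogue of the
#' P3b-driven task contrast.
#'
#' @param epochs_active,epochs_passive `lg_epochs` of the global contrast's
#'   deviant (T) condition from the participant's two sessions.
#' @inheritParams sensitivity_from_epochs
#' @return An `lg_sensitivity` with contrast
#'   `"<global contrast> (active vs passive)"`.
#' @export
active_passive_contrast <- function(epochs_active, epochs_passive,
                                    contrast = NULL, n_blocks = 50,
                                    n_iter = 1000, k = 5, seed = NULL,
                                    channels = NULL) {
  contrast <- contrast %||% epochs_active$contrast
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  prep <- function(ep) {
    ep <- block_average(ep, n_blocks)
    ep <- crop_to_window(ep, contrast$decode_window_ms)
    epochs_features(ep, channels)
  }
  Xa <- prep(epochs_active); Xp <- prep(epochs_passive)
  n <- min(nrow(Xa), nrow(Xp))
  res <- evaluate_sensitivity(Xa[seq_len(n), , drop = FALSE],
                              Xp[seq_len(n), , drop = FALSE],
                              n_iter = n_iter, k = k, seed = seed,
                              participant_id = epochs_active$participant_id,
                              contrast = paste0(contrast$name, " (active vs passive)"))
  res
}
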