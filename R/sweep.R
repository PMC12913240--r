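#' Sensor-count x epoch-fraction degradation sweep
#'
#' Evaluates active-vs-passive discriminability of the global-deviant epochs
#' over a factorial grid of montage sizes (nested 8/16/32/64 caps) crossed
#' with epoch fractions (0.25/0.5/0.75/1.0 of the available epochs, taken in
#' temporal order, emulating a shorter recording). Per configuration and
#' participant: channels are restricted to the cap, the first
#' `ceiling(fraction * n)` epochs of each session are kept, block averaging
#' is applied when enough epochs remain (otherwise the raw epochs themselves
#' serve as samples, as happens at the 25% fraction at published trial
#' counts), and accuracy is the mean over `n_repeats` re-randomized
#' stratified k-fold cross-validations of a linear SVM. The grid cell is the
#' participant mean with its standard error.
#'
#' @param participants List, one element per participant, each a list with
#'   `active` and `passive` `lg_epochs` of the global-deviant condition.
#' @param montage Full montage carrying the nested `subsets`.
#' @param sensor_counts Cap sizes to test.
#' @param fractions Epoch fractions to test.
#' @param n_repeats Cross-validation repetitions per configuration.
#' @param n_blocks Block count for block averaging.
#' @param window_ms Decoding window (ms); default 0-400 (global effects).
#' @param k Cross-validation folds.
#' @param seed Integer seed.
#' @return An `lg_sweep`: tibble of grid cells (`sensors`, `fraction`,
#'   `accuracy`, `se`) with the per-participant accuracy matrix and settings
#'   in attributes.
#' @export
run_sweep <- function(participants, montage = montage_ant64(),
                      sensor_counts = c(8, 16, 32, 64),
                      fractions = c(0.25, 0.5, 0.75, 1),
                      n_repeats = 500, n_blocks = 50,
                      window_ms = c(0, 400), k = 5, seed = NULL) {
  grid <- expand.grid(sensors = sensor_counts, fraction = fractions,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- matrix(NA_real_, length(participants), nrow(grid))

  for (p in seq_along(participants)) {
    pa <- participants[[p]]
    for (g in seq_len(nrow(grid))) {
      chans <- montage$subsets[[as.character(grid$sensors[g])]]
      if (is.null(chans)) stopf("no %d-sensor subset in montage", grid$sensors[g])
      with_seed(if (is.null(seed)) NULL else derive_seed(seed, "sweep", p, g), {
        Xy <- sweep_samples(pa$active, pa$passive, chans, grid$fraction[g],
                            n_blocks, window_ms, k)
        acc[p, g] <- mean(vapply(seq_len(n_repeats), function(i)
          cv_accuracy(Xy$X, Xy$y, k), 0))
      })
    }
  }
  out <- as_tibble(grid)
  out$accuracy <- colMeans(acc)
  out$se <- apply(acc, 2, sd) / sqrt(nrow(acc))
  attr(out, "participant_accuracy") <- acc
  attr(out, "settings") <- list(n_repeats = n_repeats, n_blocks = n_blocks,
                                window_ms = window_ms, k = k, seed = seed)
  class(out) <- c("lg_sweep", class(out))
  out
}

# Build the balanced sample matrix for one configuration: subsample epochs in
# temporal order, block-average when enough epochs are available, crop and
# flatten.
sweep_samples <- function(active, passive, channels, fraction, n_blocks,
                          window_ms, k) {
  take <- function(ep) {
    n_keep <- max(1L, ceiling(fraction * n_trials(ep)))
    ep <- subset_epochs(ep, seq_len(n_trials(ep)) <= n_keep)
    if (n_trials(ep) >= 2 * n_blocks) ep <- block_average(ep, n_blocks)
    epochs_features(crop_to_window(ep, window_ms), channels)
  }
  Xa <- take(active); Xp <- take(passive)
  n <- min(nrow(Xa), nrow(Xp))
  if (n < k) stopf("fraction %g leaves %d samples per class (< k = %d folds)",
                   fraction, n, k)
  list(X = rbind(Xa[seq_len(n), , drop = FALSE], Xp[seq_len(n), , drop = FALSE]),
       y = rep(c("active", "passive"), each = n))
}

#' Rank correlation of sweep accuracy with recording parameters
#'
#' Spearman correlation between the 16 per-configuration mean accuracies and
#' (a) the epoch fraction and (b) the sensor count, with 95% percentile
#' bootstrap confidence intervals obtained by resampling participants,
#' recomputing the grid means and the correlations per replicate.
#'
#' @param sweep An [run_sweep()] result.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return Tibble with rows `epochs` and `sensors`: `rho`, `ci_lower`,
#'   `ci_upper`, `n_boot`.
#' @export
correlate_performance <- function(sweep, n_boot = 1000, seed = NULL) {
  acc <- attr(sweep, "participant_accuracy")
  if (is.null(acc)) stopf("sweep carries no per-participant accuracies")
  rho_of <- function(m) {
    if (sd(m) == 0) return(c(NA_real_, NA_real_))
    c(suppressWarnings(cor(m, sweep$fraction, method = "spearman")),
      suppressWarnings(cor(m, sweep$sensors, method = "spearman")))
  }
  obs <- rho_of(colMeans(acc))
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(acc), replace = TRUE)
      rho_of(colMeans(acc[idx, , drop = FALSE]))
    }, c(0, 0))
  })
  ci <- apply(boots, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  tibble(parameter = c("epochs", "sensors"),
         rho = obs,
         ci_lower = ci[1, ], ci_upper = ci[2, ],
         n_boot = n_boot)
}
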