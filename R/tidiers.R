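# broom-style tidiers for the package's result objects.

#' Tidy a cluster-test result
#'
#' @param x An `lg_clusters` result.
#' @param ... Unused.
#' @return Tibble with one row per reported cluster (the `members` list
#'   column is dropped; `channels` is kept as a list column).
#' @export
tidy.lg_clusters <- function(x, ...) {
  out <- as_tibble(x)
  out$members <- NULL
  out$cluster <- seq_len(nrow(out))
  select(out, "cluster", dplyr::everything())
}

#' @rdname tidy.lg_clusters
#' @export
glance.lg_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         threshold = attr(x, "threshold"),
         alpha = attr(x, "alpha"),
         n_perm = attr(x, "n_perm"),
         n_dropped = attr(x, "n_dropped") %||% NA_integer_)
}

#' Tidy an individual-sensitivity result
#'
#' @param x An `lg_sensitivity`.
#' @param ... Unused.
#' @return Long tibble of the two accuracy distributions (`labels` =
#'   `"true"`/`"null"`, `iteration`, `accuracy`).
#' @export
tidy.lg_sensitivity <- function(x, ...) {
  bind_rows(
    tibble(labels = "true", iteration = seq_along(x$true_accuracies),
           accuracy = x$true_accuracies),
    tibble(labels = "null", iteration = seq_along(x$null_accuracies),
           accuracy = x$null_accuracies))
}

#' @rdname tidy.lg_sensitivity
#' @export
glance.lg_sensitivity <- function(x, ...) {
  tibble(participant_id = as.character(x$participant_id),
         contrast = x$contrast,
         mean_accuracy = x$mean_accuracy,
         accuracy_sd = x$accuracy_sd,
         threshold = x$threshold,
         detected = x$detected,
         p_value = x$p_value,
         n_samples = x$n_samples,
         n_features = x$n_features)
}

#' Tidy a sensor x epoch sweep
#'
#' @param x An `lg_sweep`.
#' @param ... Unused.
#' @return The grid tibble (`sensors`, `fraction`, `accuracy`, `se`).
#' @export
tidy.lg_sweep <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.lg_sweep
#' @export
glance.lg_sweep <- function(x, ...) {
  s <- attr(x, "settings")
  tibble(n_configurations = nrow(x),
         n_participants = nrow(attr(x, "participant_accuracy")),
         n_repeats = s$n_repeats, n_blocks = s$n_blocks)
}
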