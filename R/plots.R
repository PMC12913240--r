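# ggplot2 visualizations for the result objects.

#' Plot a cluster-test result
#'
#' Raster of the TFCE-enhanced statistic over channels x time with the
#' reported clusters outlined by their membership.
#'
#' @param object An `lg_clusters` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lg_clusters <- function(object, ...) {
  obs <- attr(object, "obs_tfce")
  times <- attr(object, "times")
  channels <- attr(object, "channels")
  df <- tibble(
    channel = factor(rep(channels, length(times)), levels = channels),
    time_ms = rep(times, each = length(channels)),
    stat = as.vector(obs))
  mem <- if (nrow(object)) bind_rows(object$members) else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$channel,
                                        fill = .data$stat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "TFCE") +
    ggplot2::labs(x = "time (ms)", y = NULL)
  if (!is.null(mem) && nrow(mem))
    p <- p + ggplot2::geom_point(
      data = mutate(mem, channel = factor(.data$channel, levels = channels)),
      ggplot2::aes(.data$time_ms, .data$channel), inherit.aes = FALSE,
      shape = ".", colour = "black")
  p
}

#' Plot the two accuracy distributions of a sensitivity result
#'
#' Density of the true-label and shuffled-label accuracy distributions with
#' the 95th-percentile decision threshold and the mean true accuracy.
#'
#' @param object An `lg_sensitivity`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lg_sensitivity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$accuracy, fill = .data$labels)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$mean_accuracy) +
    ggplot2::scale_fill_manual(values = c(null = "#4477aa", true = "#cc3311"),
                               name = NULL) +
    ggplot2::labs(x = "classification accuracy", y = "density",
                  title = sprintf("%s: %s", object$contrast,
                                  if (object$detected) "detected" else "not detected"))
}

#' Plot a sensor x epoch sweep grid
#'
#' Mean accuracy (with standard-error bars) against epoch fraction, one line
#' per sensor count.
#'
#' @param object An `lg_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lg_sweep <- function(object, ...) {
  df <- mutate(as_tibble(object), sensors = factor(.data$sensors))
  ggplot2::ggplot(df, ggplot2::aes(.data$fraction, .data$accuracy,
                                   colour = .data$sensors,
                                   group = .data$sensors)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$accuracy - .data$se,
                                          ymax = .data$accuracy + .data$se)) +
    ggplot2::labs(x = "fraction of epochs", y = "accuracy",
                  colour = "sensors")
}

#' ERP waveform plot at one channel
#'
#' Group-average waveforms of the two conditions at a representative
#' electrode, with reported cluster windows shaded.
#'
#' @param group An [group_data()] object.
#' @param channel Channel label.
#' @param clusters Optional `lg_clusters` whose windows to shade.
#' @param labels Condition names for the legend.
#' @return A ggplot.
#' @export
plot_erp <- function(group, channel, clusters = NULL,
                     labels = c("A", "B")) {
  ci <- match(channel, group$channels)
  if (is.na(ci)) stopf("channel '%s' not in group data", channel)
  df <- bind_rows(
    tibble(time_ms = group$times, condition = labels[1],
           uv = colMeans(group$A[, ci, , drop = FALSE][, 1, ])),
    tibble(time_ms = group$times, condition = labels[2],
           uv = colMeans(group$B[, ci, , drop = FALSE][, 1, ])))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uv,
                                        colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV)")
  if (!is.null(clusters) && nrow(clusters))
    p <- p + ggplot2::annotate("rect", xmin = clusters$onset_ms,
                               xmax = clusters$offset_ms, ymin = -Inf,
                               ymax = Inf, alpha = 0.15)
  p
}
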