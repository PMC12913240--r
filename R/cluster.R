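#' Assemble group-level data for a paired contrast
#'
#' Stacks per-participant condition-averaged waveforms into the
#' participants x channels x samples arrays used by the cluster statistics.
#' Mastoid reference channels are dropped; both conditions must contain the
#' same participants on a common time axis.
#'
#' @param A,B Lists (one element per participant) of channels x samples
#'   matrices with channel rownames, or ready-made 3-D arrays.
#' @param times Time axis (ms).
#' @param montage Montage supplying adjacency; channels are taken from the
#'   data and must exist in the montage.
#' @return An `lg_group` list (`A`, `B`, `times`, `channels`, `montage`).
#' @export
group_data <- function(A, B, times, montage) {
  to_array <- function(L) {
    if (is.array(L) && length(dim(L)) == 3) return(L)
    arr <- array(NA_real_, c(length(L), nrow(L[[1]]), ncol(L[[1]])))
    for (p in seq_along(L)) arr[p, , ] <- L[[p]]
    dimnames(arr) <- list(NULL, rownames(L[[1]]), NULL)
    arr
  }
  A <- to_array(A); B <- to_array(B)
  stopifnot(identical(dim(A), dim(B)), dim(A)[3] == length(times))
  channels <- dimnames(A)[[2]]
  if (is.null(channels)) stopf("group data needs channel names")
  keep <- !channels %in% montage$ref_labels
  structure(list(A = A[, keep, , drop = FALSE], B = B[, keep, , drop = FALSE],
                 times = times, channels = channels[keep], montage = montage),
            class = "lg_group")
}

#' Mass-univariate paired t map
#'
#' Paired t statistic of the A-B participant differences at every
#' (channel, sample) cell, n - 1 degrees of freedom. Zero-variance cells are
#' degenerate (possible in noise-free synthetic data): a cell with zero
#' variance and zero mean yields t = 0, one with a nonzero mean is capped at
#' a large finite value of the appropriate sign; both are flagged with a
#' warning.
#'
#' @param group An [group_data()] object.
#' @param t_cap Replacement magnitude for infinite t in zero-variance cells.
#' @param hat Variance-regularization fraction: each cell's standard error is
#'   floored by `hat` times the map-wide maximum standard error (the "hat"
#'   adjustment for mass-univariate t maps). 0 (the default) is the plain
#'   paired t; a small value (e.g. 0.05) stabilizes near-noise-free synthetic
#'   data at small n, where chance variance collapse otherwise produces
#'   unbounded t values.
#' @return channels x samples matrix of t values (channel rownames).
#' @export
paired_t_map <- function(group, t_cap = 1e4, hat = 0) {
  n <- dim(group$A)[1]
  if (n < 2) stopf("paired t map needs at least 2 participants")
  D <- group$A - group$B
  Dm <- matrix(D, nrow = n)                  # participants x (channels*samples)
  m <- colMeans(Dm)
  v <- (colSums(Dm^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  if (hat > 0) se <- se + hat * max(se)
  tval <- m / se
  zv <- se <= 0
  if (any(zv)) {
    warnf("%d zero-variance cells in paired t map (capped/zeroed)", sum(zv))
      tval[zv] <- ifelse(abs(m[zv]) > 0, sign(m[zv]) * t_cap, 0)
  }
  matrix(tval, dim(group$A)[2], dim(group$A)[3],
         dimnames = list(group$channels, NULL))
}

#' Threshold-free cluster enhancement
#'
#' Enhances a channels x samples statistic map: for each point p and each
#' sign separately, integrates extent^E * height^H over all thresholds
#' h = dh, 2 dh, ... up to the map maximum, where the extent is the size of
#' the spatiotemporal connected component containing p at threshold h
#' (channel adjacency crossed with temporal adjacency of consecutive
#' samples). Negative parts are enhanced on the absolute value and
#' re-signed. E = 0.5, H = 2 are the method's canonical parameters; the step
#' defaults to max|map| / 50.
#'
#' @param map channels x samples numeric matrix.
#' @param adjacency An `lg_montage`, an adjacency matrix over the map's
#'   channels, or a 0-based neighbor list.
#' @param E,H Extent and height exponents.
#' @param dh Integration step; `NULL` for max|map| / n_steps.
#' @param n_steps Number of integration steps used when `dh` is `NULL`.
#' @return Enhanced map, same shape and sign structure as `map`.
#' @export
tfce <- function(map, adjacency, E = 0.5, H = 2, dh = NULL, n_steps = 50) {
  if (length(map) == 0) stopf("empty statistic map")
  adj <- as_adjacency_list(adjacency, rownames(map), nrow(map))
  if (is.null(dh)) {
    mx <- max(abs(map))
    if (mx == 0) return(map * 0)
    dh <- mx / n_steps
  }
  out <- tfce_cpp(map, adj, E, H, dh)
  dimnames(out) <- dimnames(map)
  out
}

as_adjacency_list <- function(adjacency, channels, n_ch) {
  if (inherits(adjacency, "lg_montage")) {
    if (is.null(channels)) stopf("map needs channel rownames to use a montage")
    return(adjacency_list(adjacency, channels))
  }
  if (is.matrix(adjacency)) {
    stopifnot(nrow(adjacency) == n_ch)
    return(lapply(seq_len(n_ch), function(i) as.integer(which(adjacency[i, ])) - 1L))
  }
  stopifnot(is.list(adjacency), length(adjacency) == n_ch)
  lapply(adjacency, as.integer)
}

#' Cluster-based permutation test with TFCE
#'
#' Group-level paired test between two condition-averaged waveform sets. The
#' observed paired t map is TFCE-enhanced; the null distribution of the
#' maximum absolute enhanced statistic is built by randomly sign-flipping
#' participants' difference waveforms (the observed labeling is always
#' included in the null). Points whose absolute enhanced statistic exceeds
#' the (1 - alpha) null quantile are significant (two-tailed via the
#' absolute-maximum statistic); the significant mask is then reduced to
#' clusters and reported only where at least `min_adjacent_channels`
#' mutually neighboring channels are significant at some common time point
#' and the cluster persists for at least `min_duration_ms`.
#'
#' @param group An [group_data()] object.
#' @param n_perm Number of permutations (observed labeling included).
#' @param alpha Significance level (two-tailed).
#' @param seed Integer seed for the sign flips.
#' @param E,H,n_steps TFCE parameters (see [tfce()]); the integration step is
#'   each map's own max / `n_steps`.
#' @param min_duration_ms Minimum cluster duration (ms).
#' @param min_adjacent_channels Minimum count of mutually adjacent
#'   significant channels required at some time point.
#' @param method `"auto"` (default) enumerates all `2^n` sign patterns
#'   exactly when that is no more work than `n_perm` random draws, otherwise
#'   samples; `"exhaustive"` and `"monte-carlo"` force the choice.
#' @param hat Variance-regularization fraction passed to the t computation
#'   (see [paired_t_map()]); applied identically to the observed and every
#'   permuted map, so exchangeability is preserved.
#' @return An `lg_clusters` tibble: one row per reported cluster with
#'   `polarity`, `onset_ms`, `offset_ms`, `duration_ms`, `n_channels`,
#'   `channels` (list), `peak_stat` (signed peak enhanced statistic),
#'   `peak_latency_ms`, `peak_channel`, `p_value` and a `members` list
#'   column; attributes carry the threshold, the null maxima, and the
#'   enhanced observed map.
#' @export
permutation_test <- function(group, n_perm = 1000, alpha = 0.05, seed = NULL,
                             E = 0.5, H = 2, n_steps = 50,
                             min_duration_ms = 20, min_adjacent_channels = 2,
                             method = c("auto", "monte-carlo", "exhaustive"),
                             hat = 0) {
  method <- match.arg(method)
  n <- dim(group$A)[1]
  if (n < 2) stopf("need at least 2 participants")
  exhaustive <- switch(method,
    auto = n <= 30 && 2^n <= n_perm,
    exhaustive = TRUE,
    `monte-carlo` = FALSE)
  if (exhaustive && n > 20)
    stopf("exhaustive enumeration over 2^%d sign patterns is not tractable", n)
  if (!exhaustive && n_perm < 100)
    warnf("n_perm = %d is low; null quantiles will be coarse", n_perm)
  adj <- adjacency_list(group$montage, group$channels)
  n_ch <- dim(group$A)[2]; n_s <- dim(group$A)[3]
  D <- matrix(group$A - group$B, nrow = n)
  ssq <- colSums(D^2)

  t_of_signs <- function(s) {
    m <- as.vector(crossprod(D, s)) / n
    v <- (ssq - n * m^2) / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    if (hat > 0) se <- se + hat * max(se)
    bad <- se <= 1e-12
    se[bad] <- 1
    tval <- m / se
    tval[bad] <- ifelse(abs(m[bad]) > 0, sign(m[bad]) * 1e4, 0)
    matrix(tval, n_ch, n_s)
  }
  tfce_of <- function(tm) {
    mx <- max(abs(tm))
    if (mx == 0) return(tm)
    tfce_cpp(tm, adj, E, H, mx / n_steps)
  }

  obs_t <- t_of_signs(rep(1, n))
  obs_tfce <- tfce_of(obs_t)
  dimnames(obs_tfce) <- list(group$channels, NULL)

  if (exhaustive) {
    # Every sign pattern once: the null (and hence every p) is exact.
    signs_all <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_max <- apply(signs_all, 1, function(s)
      max(abs(tfce_of(t_of_signs(s)))))
    n_perm <- length(null_max)
  } else {
    null_max <- numeric(n_perm)
    null_max[1] <- max(abs(obs_tfce))      # observed labeling in the null
    with_seed(seed, {
      for (i in seq_len(n_perm - 1)) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        null_max[i + 1] <- max(abs(tfce_of(t_of_signs(s))))
      }
    })
  }

  threshold <- unname(quantile(null_max, 1 - alpha))
  clusters <- extract_clusters(obs_tfce, threshold, adj, group$times,
                               group$channels, group$montage, null_max,
                               min_duration_ms, min_adjacent_channels)
  attr(clusters, "threshold") <- threshold
  attr(clusters, "null_max") <- null_max
  attr(clusters, "alpha") <- alpha
  attr(clusters, "n_perm") <- n_perm
  attr(clusters, "times") <- group$times
  attr(clusters, "channels") <- group$channels
  attr(clusters, "obs_tfce") <- obs_tfce
  attr(clusters, "obs_t") <- obs_t
  class(clusters) <- c("lg_clusters", class(clusters))
  clusters
}

extract_clusters <- function(obs_tfce, threshold, adj, times, channels,
                             montage, null_max, min_duration_ms,
                             min_adjacent_channels) {
  A <- montage$adjacency[channels, channels, drop = FALSE]
  rows <- list()
  n_dropped <- 0L
  for (pol in c("positive", "negative")) {
    mask <- if (pol == "positive") obs_tfce > threshold else -obs_tfce > threshold
    if (!any(mask)) next
    lab <- components_cpp(mask, adj)
    for (k in seq_len(max(lab))) {
      sel <- lab == k
      ts <- which(colSums(sel) > 0)
      onset <- times[min(ts)]; offset <- times[max(ts)]
      # >= min_adjacent_channels mutually adjacent channels at one time point
      ok_adj <- FALSE
      if (min_adjacent_channels <= 1) ok_adj <- TRUE else for (t_i in ts) {
        chs <- which(sel[, t_i])
        if (length(chs) >= min_adjacent_channels &&
            any(A[chs, chs, drop = FALSE])) { ok_adj <- TRUE; break }
      }
      if (offset - onset < min_duration_ms || !ok_adj) {
        n_dropped <- n_dropped + 1L
        next
      }
      peak_i <- which.max(abs(obs_tfce) * sel)
      pk <- arrayInd(peak_i, dim(obs_tfce))
      mem_idx <- which(sel, arr.ind = TRUE)
      member_tbl <- tibble(channel = channels[mem_idx[, 1]],
                           time_ms = times[mem_idx[, 2]])
      cluster_channels <- channels[which(rowSums(sel) > 0)]
      peak_channel <- channels[pk[1]]
      rows[[length(rows) + 1]] <- tibble(
        polarity = pol,
        onset_ms = onset, offset_ms = offset, duration_ms = offset - onset,
        n_channels = length(cluster_channels),
        channels = list(cluster_channels),
        peak_stat = obs_tfce[peak_i],
        peak_latency_ms = times[pk[2]],
        peak_channel = peak_channel,
        p_value = mean(null_max >= abs(obs_tfce[peak_i])),
        members = list(member_tbl)
      )
    }
  }
  out <- if (length(rows)) arrange(bind_rows(rows), .data$onset_ms)
         else tibble(polarity = character(), onset_ms = double(),
                     offset_ms = double(), duration_ms = double(),
                     n_channels = integer(), channels = list(),
                     peak_stat = double(), peak_latency_ms = double(),
                     peak_channel = character(), p_value = double(),
                     members = list())
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-cluster report at a representative electrode
#'
#' Restricts each cluster to one channel's time course (the published
#' convention: global effects at Pz, everything else at Fz) and reports its
#' onset, offset, peak enhanced statistic and peak latency there; clusters
#' that never include the channel are flagged absent.
#'
#' @param result An `lg_clusters` result.
#' @param channel Channel label.
#' @return Tibble with one row per cluster (`present`, `onset_ms`,
#'   `offset_ms`, `peak_stat`, `peak_latency_ms`).
#' @export
report_representative <- function(result, channel) {
  channels <- attr(result, "channels")
  if (!channel %in% channels) stopf("channel '%s' not in result", channel)
  obs <- attr(result, "obs_tfce")
  purrr::imap(result$members, function(mem, i) {
    at <- mem[mem$channel == channel, ]
    if (nrow(at) == 0)
      return(tibble(cluster = i, channel = channel, present = FALSE,
                    onset_ms = NA_real_, offset_ms = NA_real_,
                    peak_stat = NA_real_, peak_latency_ms = NA_real_))
    vals <- obs[channel, match(at$time_ms, attr(result, "times"))]
    tibble(cluster = i, channel = channel, present = TRUE,
           onset_ms = min(at$time_ms), offset_ms = max(at$time_ms),
           peak_stat = vals[which.max(abs(vals))],
           peak_latency_ms = at$time_ms[which.max(abs(vals))])
  }) |> bind_rows()
}
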