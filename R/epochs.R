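#' Epoch container
#'
#' Holds a trials x channels x samples array with its time axis (ms relative
#' to the lock event), baseline window, channel labels and per-trial
#' metadata. Constructed by [extract_epochs()] or directly (e.g. for
#' simulation-free tests).
#'
#' @param data trials x channels x samples numeric array (microvolts).
#' @param times Time axis in ms (length = third dimension).
#' @param channels Channel labels (length = second dimension).
#' @param baseline_ms Length-2 baseline window in ms, or `NULL` if already
#'   corrected / not applicable.
#' @param label Condition tag for all trials (or a per-trial vector).
#' @param participant_id,contrast Metadata carried along.
#' @param pair_index Optional per-trial pair indices.
#' @param ref_labels Channels excluded from analysis/rejection (references).
#' @return An `lg_epochs` object.
#' @export
epoch_set <- function(data, times, channels, baseline_ms = NULL,
                      label = NA_character_, participant_id = NA,
                      contrast = NA_character_, pair_index = NULL,
                      ref_labels = character()) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times),
            dim(data)[2] == length(channels))
  if (length(label) == 1) label <- rep(label, dim(data)[1])
  structure(list(data = data, times = times, channels = channels,
                 baseline_ms = baseline_ms, label = label,
                 participant_id = participant_id, contrast = contrast,
                 pair_index = pair_index %||% seq_len(dim(data)[1]),
                 ref_labels = ref_labels),
            class = "lg_epochs")
}

#' @export
print.lg_epochs <- function(x, ...) {
  cat(sprintf("<lg_epochs> %d trials x %d channels x %d samples [%g..%g ms] %s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times),
              if (is.na(x$contrast)) "" else x$contrast))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

#' The five analysis contrasts
#'
#' Each contrast names a condition pair (A = test condition, B = control),
#' the event the epochs are locked to, the epoch geometry and the
#' classification window:
#' \describe{
#'   \item{P1N1P2}{first standard stimulus (epoch -100..350 ms, baseline
#'     -100..0) vs the resting-state interval immediately preceding it
#'     (-450..0 ms, baseline -450..-350); decoding window 0-300 ms.}
#'   \item{Local_SF / Local_ST}{second (deviant) stimulus of S-F / S-T pairs
#'     vs the first standard of the same pair, same 450-ms geometry;
#'     decoding window 0-300 ms.}
#'   \item{Global_SS_ST1 / Global_SF_ST2}{train deviant T of S-T pairs in
#'     S-S / S-F context vs the second stimulus of the immediately preceding
#'     context pair, 900-ms epochs (-100..800 ms) locked to the second
#'     stimulus; decoding window 0-400 ms.}
#' }
#'
#' @param name One of `"P1N1P2"`, `"Local_SF"`, `"Local_ST"`,
#'   `"Global_SS_ST1"`, `"Global_SF_ST2"`.
#' @return An `lg_contrast` list (name, windows in ms, decode window).
#' @export
contrast_spec <- function(name = c("P1N1P2", "Local_SF", "Local_ST",
                                   "Global_SS_ST1", "Global_SF_ST2")) {
  name <- match.arg(name)
  local_span <- c(-100, 348)        # 450-ms epoch realized on the 4-ms grid
  global_span <- c(-100, 796)       # 900-ms epoch
  spec <- switch(name,
    P1N1P2 = list(span_a = local_span, baseline_a = c(-100, 0),
                  span_b = c(-448, 0), baseline_b = c(-450, -350),
                  decode_window_ms = c(0, 300)),
    Local_SF = , Local_ST =
      list(span_a = local_span, baseline_a = c(-100, 0),
           span_b = local_span, baseline_b = c(-100, 0),
           decode_window_ms = c(0, 300)),
    Global_SS_ST1 = , Global_SF_ST2 =
      list(span_a = global_span, baseline_a = c(-100, 0),
           span_b = global_span, baseline_b = c(-100, 0),
           decode_window_ms = c(0, 400)))
  structure(c(list(name = name), spec), class = "lg_contrast")
}

#' Extract the paired epoch sets of a contrast
#'
#' Cuts baseline-corrected epochs for the two conditions of a contrast from a
#' preprocessed recording. Trials are paired by construction (trial i of A
#' corresponds to trial i of B): S with its own preceding resting state,
#' within-pair deviant with the same pair's standard, each global deviant
#' with its immediately preceding context pair. Trials whose window falls
#' outside the recording are dropped from both sets.
#'
#' @param raw A preprocessed `lg_recording` (see [filter_chain()]).
#' @param contrast An [contrast_spec()] or its name.
#' @param participant_id Carried into the epoch sets.
#' @return List with elements `A` and `B` (`lg_epochs`).
#' @export
extract_epochs <- function(raw, contrast, participant_id = NA) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  sch <- raw$events
  an <- sch[sch$analyzed, ]
  firsts <- an[an$position == "first", ]
  seconds <- an[an$position == "second", ]
  all_seconds <- sch[sch$position == "second", ]

  pick <- switch(contrast$name,
    P1N1P2 = {
      list(a_on = firsts$onset_ms, b_on = firsts$onset_ms,
           pair = firsts$pair_index, lab = c("S", "RS"))
    },
    Local_SF = , Local_ST = {
      pt <- if (contrast$name == "Local_SF") "SF" else "ST"
      sel <- seconds$pair_type == pt
      p <- seconds$pair_index[sel]
      list(a_on = seconds$onset_ms[sel],
           b_on = firsts$onset_ms[match(p, firsts$pair_index)],
           pair = p,
           lab = c(if (pt == "SF") "F" else "T", "S"))
    },
    Global_SS_ST1 = , Global_SF_ST2 = {
      ctx <- if (contrast$name == "Global_SS_ST1") "SS" else "SF"
      sel <- seconds$pair_type == "ST" & !is.na(seconds$global_context) &
        seconds$global_context == ctx
      p <- seconds$pair_index[sel]
      prev <- match(p - 1L, all_seconds$pair_index)
      ok <- !is.na(prev) & all_seconds$pair_type[prev] == ctx
      list(a_on = seconds$onset_ms[sel][ok], b_on = all_seconds$onset_ms[prev[ok]],
           pair = p[ok],
           lab = c("T", if (ctx == "SS") "S" else "F"))
    })
  if (length(pick$a_on) == 0)
    stopf("contrast %s: no qualifying trials in this schedule", contrast$name)

  A <- cut_epochs(raw, pick$a_on, contrast$span_a, contrast$baseline_a)
  B <- cut_epochs(raw, pick$b_on, contrast$span_b, contrast$baseline_b)
  keep <- A$keep & B$keep
  if (!any(keep))
    stopf("contrast %s: all trials fall outside the recording", contrast$name)
  make <- function(E, lab, span) epoch_set(
    E$data[keep, , , drop = FALSE], E$times, rownames(raw$data),
    baseline_ms = NULL, label = lab, participant_id = participant_id,
    contrast = contrast$name, pair_index = pick$pair[keep],
    ref_labels = raw$montage$ref_labels)
  list(A = make(A, pick$lab[1]), B = make(B, pick$lab[2]))
}

# Cut and baseline-correct epochs around lock onsets. Returns the data for
# all requested trials plus a keep mask for windows inside the recording.
cut_epochs <- function(raw, lock_onsets_ms, span_ms, baseline_ms) {
  dt <- 1000 / raw$srate
  rel <- seq(round(span_ms[1] / dt), round(span_ms[2] / dt))
  times <- rel * dt
  lock <- round(lock_onsets_ms / dt) + 1L
  n <- ncol(raw$data)
  n_tr <- length(lock)
  n_ch <- nrow(raw$data)
  keep <- lock + rel[1] >= 1 & lock + rel[length(rel)] <= n
  data <- array(NA_real_, c(n_tr, n_ch, length(rel)))
  bl <- which(times >= baseline_ms[1] & times <= baseline_ms[2])
  if (length(bl) == 0) stopf("baseline window outside epoch span")
  for (i in which(keep)) {
    seg <- raw$data[, lock[i] + rel, drop = FALSE]
    data[i, , ] <- seg - rowMeans(seg[, bl, drop = FALSE])
  }
  list(data = data, times = times, keep = keep, baseline_ms = baseline_ms)
}

#' Amplitude-based artifact rejection with matched counts
#'
#' Drops every trial whose absolute voltage exceeds `threshold_uv` on any
#' non-reference channel at any sample. With `matched = TRUE` (the default,
#' and the published procedure) the two sets are treated as paired: a
#' rejection in either member removes the trial from both, so the counts
#' stay equal.
#'
#' @param A,B Paired `lg_epochs` (equal trial counts when `matched`).
#' @param threshold_uv Rejection threshold (microvolts).
#' @param matched Reject concurrently across the pair.
#' @return List with cleaned `A` and `B` and the number rejected.
#' @export
reject_amplitude <- function(A, B, threshold_uv = 100, matched = TRUE) {
  if (matched && n_trials(A) != n_trials(B))
    stopf("matched rejection requires equal trial counts (%d vs %d)",
          n_trials(A), n_trials(B))
  bad_a <- epochs_exceeding(A, threshold_uv)
  bad_b <- epochs_exceeding(B, threshold_uv)
  if (matched) {
    bad <- bad_a | bad_b
    keep_a <- keep_b <- !bad
  } else {
    keep_a <- !bad_a
    keep_b <- !bad_b
  }
  if (!any(keep_a) || !any(keep_b))
    stopf("amplitude rejection at %g uV removed every trial", threshold_uv)
  list(A = subset_epochs(A, keep_a), B = subset_epochs(B, keep_b),
       n_rejected = c(A = sum(!keep_a), B = sum(!keep_b)))
}

epochs_exceeding <- function(ep, threshold_uv) {
  ch <- which(!ep$channels %in% ep$ref_labels)
  apply(abs(ep$data[, ch, , drop = FALSE]), 1, max) > threshold_uv
}

subset_epochs <- function(ep, keep) {
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$label <- ep$label[keep]
  ep$pair_index <- ep$pair_index[keep]
  ep
}

#' Average an epoch set over trials
#'
#' @param ep An `lg_epochs`.
#' @return channels x samples matrix of the trial-averaged waveform.
#' @export
epochs_average <- function(ep) {
  out <- apply(ep$data, c(2, 3), mean)
  dimnames(out) <- list(ep$channels, NULL)
  out
}
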