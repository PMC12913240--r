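#' Background-activity specification for the EEG simulator
#'
#' The noise model is spatially correlated 1/f ("pink") broadband activity
#' plus a posterior-dominant alpha rhythm, with optional large-amplitude
#' excursions for exercising artifact rejection. It is a stand-in for ongoing
#' EEG sufficient to validate the analysis pipeline, not a biophysical model.
#'
#' @param one_over_f_exponent Spectral exponent of the broadband background
#'   (power ~ 1/f^exponent); 1 is typical of scalp EEG.
#' @param broadband_sd_uv Per-channel SD of the broadband background
#'   (microvolts).
#' @param alpha_amplitude_uv Peak amplitude of the alpha rhythm at its
#'   posterior maximum (microvolts).
#' @param alpha_freq_hz Alpha frequency (Hz).
#' @param spatial_smoothing Correlation between channels' broadband noise,
#'   in \[0, 1): implemented by mixing an independent and a shared component
#'   with weights `sqrt(1 - s)` and `sqrt(s)`.
#' @param artifact_rate Fraction of pairs receiving a +/-150 microvolt
#'   excursion on one random channel (for rejection testing; 0 by default).
#' @return An `lg_noise_spec` list.
#' @export
noise_spec <- function(one_over_f_exponent = 1,
                       broadband_sd_uv = 6,
                       alpha_amplitude_uv = 3,
                       alpha_freq_hz = 10,
                       spatial_smoothing = 0.3,
                       artifact_rate = 0) {
  stopifnot(one_over_f_exponent >= 0, broadband_sd_uv >= 0,
            alpha_amplitude_uv >= 0, alpha_freq_hz > 0,
            spatial_smoothing >= 0, spatial_smoothing < 1,
            artifact_rate >= 0, artifact_rate <= 1)
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 broadband_sd_uv = broadband_sd_uv,
                 alpha_amplitude_uv = alpha_amplitude_uv,
                 alpha_freq_hz = alpha_freq_hz,
                 spatial_smoothing = spatial_smoothing,
                 artifact_rate = artifact_rate),
            class = "lg_noise_spec")
}

# 1/f-shaped unit-variance noise via frequency-domain shaping of white
# Gaussian noise. The (real, symmetric) shaping vector is memoized per
# length/exponent, and two independent series are produced per FFT pair by
# packing them into the real and imaginary parts.
.lg_cache <- new.env(parent = emptyenv())

pink_amp <- function(nf, exponent) {
  key <- sprintf("amp_%d_%g", nf, exponent)
  if (!is.null(.lg_cache[[key]])) return(.lg_cache[[key]])
  f <- seq(0, nf - 1) / nf
  f <- pmin(f, 1 - f)                      # two-sided frequency magnitude
  amp <- c(0, f[-1]^(-exponent / 2))
  .lg_cache[[key]] <- amp
  amp
}

# n x n_series matrix (series in columns) of independent unit-SD 1/f series.
pink_matrix <- function(n_series, n, exponent) {
  nf <- stats::nextn(n, 2)
  amp <- pink_amp(nf, exponent)
  # Analytic scale: for x = ifft(amp * w) with white complex w, the real and
  # imaginary parts each have SD sqrt(sum(amp^2) / 2) at every sample.
  scl <- sqrt(sum(amp^2) / 2)
  out <- matrix(NA_real_, n, n_series)
  i <- 1L
  while (i <= n_series) {
    # White complex spectrum (no Hermitian symmetry needed: the real and
    # imaginary parts of the inverse transform are two independent series
    # with the shaped spectrum).
    w <- complex(real = rnorm(nf), imaginary = rnorm(nf))
    x <- fft(amp * w, inverse = TRUE)[seq_len(n)] / scl
    out[, i] <- Re(x)
    if (i + 1L <= n_series) out[, i + 1L] <- Im(x)
    i <- i + 2L
  }
  out
}

#' Simulate a continuous multichannel EEG recording
#'
#' Sums, for every component, a Gaussian-envelope deflection at each
#' qualifying event (per-channel topography gain, trial-jittered latency)
#' with the background activity of [noise_spec()], then expresses all
#' channels against the CPz online reference (CPz itself becomes flat;
#' mastoids carry background activity only). Units are microvolts throughout;
#' sampling rate 1000 Hz.
#'
#' Determinism: each component and the noise draw from independent streams
#' derived from `seed`, so a simulation with components A and B equals the
#' sum of an A-only and a B-only simulation minus their shared noise
#' realization, sample for sample.
#'
#' @param schedule An `lg_schedule` with onsets assigned.
#' @param components Tibble of component specs (rows from [component_spec()]).
#' @param noise An [noise_spec()].
#' @param montage An [montage_ant64()] montage.
#' @param seed Integer seed.
#' @param condition Task condition; defaults to the schedule's label. Governs
#'   components whose rule is active-only.
#' @param srate Sampling rate in Hz.
#' @return An `lg_recording`: list with `data` (channels x samples matrix,
#'   microvolts), `srate`, `montage`, `events`, `reference`, `condition`.
#' @export
simulate_recording <- function(schedule, components, noise = noise_spec(),
                               montage = montage_ant64(), seed = NULL,
                               condition = attr(schedule, "condition") %||% "passive",
                               srate = 1000) {
  if (anyNA(schedule$onset_ms)) stopf("schedule has no onsets; run assign_onsets()")
  n_ch <- length(montage$labels)
  dur_ms <- max(schedule$onset_ms) + 1000
  n <- ceiling(dur_ms / 1000 * srate) + 1L
  seed <- seed %||% derive_seed(stats::runif(1, 1, 2^30), "auto")

  # Accumulate in samples x channels orientation (contiguous channel columns),
  # transpose once at the end.
  sources <- list()   # per component: unit source series (length n)
  gains <- list()     # per component: length-n_ch gain vector
  for (i in seq_len(nrow(components))) {
    comp <- components[i, ]
    ev <- component_events(schedule, comp$applies_to, condition)
    if (nrow(ev) == 0 || comp$amplitude_uv == 0) next
    with_seed(derive_seed(seed, "component", comp$name), {
      jit <- rnorm(nrow(ev), 0, comp$latency_jitter_sd_ms)
      sds <- comp$half_width_ms / 2.355
      half_len <- ceiling(3.5 * sds / 1000 * srate)
      src <- numeric(n)
      centers <- (ev$onset_ms + comp$peak_latency_ms + jit) / 1000 * srate + 1
      for (k in seq_along(centers)) {
        c0 <- round(centers[k])
        idx <- max(1L, c0 - half_len):min(n, c0 + half_len)
        if (length(idx) == 0) next
        t_ms <- (idx - centers[k]) / srate * 1000
        src[idx] <- src[idx] + exp(-0.5 * (t_ms / sds)^2)
      }
      sources[[length(sources) + 1L]] <- src
      gains[[length(gains) + 1L]] <- comp$amplitude_uv *
        topography_gain(montage, comp$topography)
    })
  }
  Xt <- if (length(sources))
    do.call(cbind, sources) %*% do.call(rbind, gains)
  else matrix(0, n, n_ch)

  with_seed(derive_seed(seed, "noise"), {
    if (noise$broadband_sd_uv > 0) {
      s <- noise$spatial_smoothing
      common <- pink_matrix(1L, n, noise$one_over_f_exponent)[, 1]
      shared <- noise$broadband_sd_uv * sqrt(s) * common
      own_w <- noise$broadband_sd_uv * sqrt(1 - s)
      # channels in small chunks to keep peak memory bounded
      ch <- 1L
      while (ch <= n_ch) {
        j <- ch:min(n_ch, ch + 7L)
        P <- pink_matrix(length(j), n, noise$one_over_f_exponent)
        Xt[, j] <- Xt[, j] + own_w * P + shared
        ch <- ch + 8L
      }
    }
    if (noise$alpha_amplitude_uv > 0) {
      tt <- seq_len(n) / srate
      phase <- runif(1, 0, 2 * pi)
      wave <- noise$alpha_amplitude_uv *
        sin(2 * pi * noise$alpha_freq_hz * tt + phase)
      g <- alpha_gain(montage)
      for (c_i in which(g > 0)) Xt[, c_i] <- Xt[, c_i] + g[c_i] * wave
    }
    if (noise$artifact_rate > 0) {
      firsts <- schedule[schedule$position == "first", ]
      hit <- which(runif(nrow(firsts)) < noise$artifact_rate)
      scalp_idx <- which(!montage$labels %in% montage$ref_labels)
      for (p in hit) {
        ch <- sample_vec(scalp_idx, 1)
        c0 <- round(firsts$onset_ms[p] / 1000 * srate + 1 + runif(1, 0, 0.3 * srate))
        idx <- max(1L, c0 - 100L):min(n, c0 + 100L)
        Xt[idx, ch] <- Xt[idx, ch] +
          sample(c(-150, 150), 1) * exp(-0.5 * ((idx - c0) / 30)^2)
      }
    }
  })

  # Online CPz reference: recorded potentials are differences against CPz.
  Xt <- Xt - Xt[, match(montage$online_ref, montage$labels)]
  X <- t(Xt)
  dimnames(X) <- list(montage$labels, NULL)
  structure(list(data = X, srate = srate, montage = montage,
                 events = schedule, reference = montage$online_ref,
                 condition = condition),
            class = "lg_recording")
}

# Posterior-maximum alpha gain profile (zero at the mastoid references).
alpha_gain <- function(montage) {
  anchor <- montage$pos["Oz", ]
  d <- acos(pmin(1, pmax(-1, as.vector(montage$pos %*% anchor))))
  g <- exp(-0.5 * (d / 0.8)^2)
  g[montage$labels %in% montage$ref_labels] <- 0
  setNames(g, montage$labels)
}

#' Simulate one participant's active and passive sessions
#'
#' Draws the participant's idiosyncrasies once — a multiplicative amplitude
#' factor and an additive latency shift per component — and applies them to
#' both sessions, whose stimulus schedules are identical (as in the published
#' design, where the same auditory sequence is presented under both task
#' conditions).
#'
#' @param config A [paradigm_config()].
#' @param noise An [noise_spec()].
#' @param montage Montage.
#' @param participant_id Identifier (integer or string).
#' @param seed Master seed; the participant's schedule, perturbation and the
#'   two sessions' noise are all derived from it and `participant_id`.
#' @param between_subject_sd SD of the multiplicative amplitude perturbation
#'   (fraction of the mean; default 0.2).
#' @param latency_shift_sd_ms SD of the per-component latency shift (ms).
#' @param components_active,components_passive Component tables; defaults to
#'   [build_default_components()] per condition.
#' @return List with `participant_id`, `active` and `passive`
#'   `lg_recording`s, and the drawn `perturbation` tibble.
#' @export
simulate_participant <- function(config = paradigm_config(),
                                 noise = noise_spec(),
                                 montage = montage_ant64(),
                                 participant_id = 1,
                                 seed = 1,
                                 between_subject_sd = 0.2,
                                 latency_shift_sd_ms = 5,
                                 components_active = build_default_components("active"),
                                 components_passive = build_default_components("passive")) {
  sch_seed <- derive_seed(seed, "schedule", participant_id)
  schedule_active <- generate_session(config, "active", seed = sch_seed)
  schedule_passive <- generate_session(config, "passive", seed = sch_seed)

  all_names <- sort(unique(c(components_active$name, components_passive$name)))
  pert <- with_seed(derive_seed(seed, "participant", participant_id), {
    tibble(name = all_names,
           amp_factor = pmax(0.1, 1 + rnorm(length(all_names), 0, between_subject_sd)),
           latency_shift_ms = rnorm(length(all_names), 0, latency_shift_sd_ms))
  })
  perturb <- function(specs) {
    j <- match(specs$name, pert$name)
    specs$amplitude_uv <- specs$amplitude_uv * pert$amp_factor[j]
    specs$peak_latency_ms <- specs$peak_latency_ms + pert$latency_shift_ms[j]
    specs
  }
  list(
    participant_id = participant_id,
    active = simulate_recording(schedule_active, perturb(components_active),
                                noise, montage,
                                seed = derive_seed(seed, "rec", participant_id, "active")),
    passive = simulate_recording(schedule_passive, perturb(components_passive),
                                 noise, montage,
                                 seed = derive_seed(seed, "rec", participant_id, "passive")),
    perturbation = pert
  )
}

#' Simulate a cohort of participants
#'
#' Convenience wrapper around [simulate_participant()]; note that a
#' full-scale cohort (30 participants, 1380 pairs, two sessions) holds
#' gigabytes of continuous data — for large studies process participants one
#' at a time (as [run_study()] does) instead.
#'
#' @inheritParams simulate_participant
#' @param n_participants Number of participants.
#' @return List of participant objects (see [simulate_participant()]).
#' @export
simulate_cohort <- function(n_participants, config = paradigm_config(),
                            noise = noise_spec(), montage = montage_ant64(),
                            between_subject_sd = 0.2, seed = 1, ...) {
  stopifnot(n_participants >= 1)
  lapply(seq_len(n_participants), function(p)
    simulate_participant(config, noise, montage, participant_id = p,
                         seed = seed, between_subject_sd = between_subject_sd,
                         ...))
}
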