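#' ERP component specifications
#'
#' A component is a Gaussian-envelope deflection added to the continuous
#' signal at qualifying events: signed peak amplitude (microvolts), peak
#' latency relative to stimulus onset, half width (full width at half maximum
#' of the envelope), a scalp topography gain profile in \[0, 1\], a trial-wise
#' latency jitter, and a rule (`applies_to`) selecting which events elicit it.
#'
#' @param name Component label (`"P1"`, `"N1"`, `"P2"`, `"MMN"`, `"P3a"`,
#'   `"P3b"`, or any custom label).
#' @param peak_latency_ms Peak latency after stimulus onset (ms).
#' @param half_width_ms Full width at half maximum of the Gaussian envelope
#'   (ms); the Gaussian SD is `half_width_ms / 2.355`.
#' @param amplitude_uv Signed peak amplitude (microvolts) at the
#'   topography maximum.
#' @param topography `"frontocentral"` or `"centroparietal"` gain profile.
#' @param applies_to Which events elicit the component: `"all_stimuli"`,
#'   `"deviant_second"` (second stimulus of S-F and S-T pairs),
#'   `"st_second"` (second stimulus of S-T pairs), or `"st_second_active"`
#'   (same, active condition only).
#' @param latency_jitter_sd_ms Trial-to-trial SD of the peak latency (ms).
#' @return One-row tibble describing the component.
#' @export
component_spec <- function(name, peak_latency_ms, half_width_ms, amplitude_uv,
                           topography = c("frontocentral", "centroparietal"),
                           applies_to = c("all_stimuli", "deviant_second",
                                          "st_second", "st_second_active"),
                           latency_jitter_sd_ms = 10) {
  topography <- match.arg(topography)
  applies_to <- match.arg(applies_to)
  if (half_width_ms <= 0) stopf("half_width_ms must be > 0")
  tibble(name = name, peak_latency_ms = peak_latency_ms,
         half_width_ms = half_width_ms, amplitude_uv = amplitude_uv,
         topography = topography, applies_to = applies_to,
         latency_jitter_sd_ms = latency_jitter_sd_ms)
}

#' Default component set for one task condition
#'
#' The obligatory P1/N1/P2 complex is attached to every stimulus; the mismatch
#' negativity (MMN, negative frontocentral) to the second stimulus of every
#' deviant pair (S-F and S-T); the P3a (positive frontocentral) to the second
#' stimulus of S-T pairs; and the P3b (positive centroparietal) to the second
#' stimulus of S-T pairs in the active condition only, reflecting its
#' dependence on voluntary target evaluation. Default peak latencies are
#' 76/124/184/148/248/330 ms.
#'
#' Amplitudes are free parameters of the simulation (no published effect
#' sizes in microvolts exist for this design); the defaults are chosen to
#' give realistic single-trial SNR against the default noise model.
#'
#' @param condition `"active"` or `"passive"`.
#' @return Tibble of component specs (one row per component).
#' @export
#' @examples
#' setdiff(build_default_components("active")$name,
#'         build_default_components("passive")$name)   # "P3b"
build_default_components <- function(condition = c("active", "passive")) {
  condition <- match.arg(condition)
  specs <- bind_rows(
    component_spec("P1",   76, 40,  2.0, "frontocentral", "all_stimuli"),
    component_spec("N1",  124, 50, -4.0, "frontocentral", "all_stimuli"),
    component_spec("P2",  184, 70,  3.0, "frontocentral", "all_stimuli"),
    component_spec("MMN", 148, 70, -3.0, "frontocentral", "deviant_second"),
    component_spec("P3a", 248, 90,  4.0, "frontocentral", "st_second"),
    component_spec("P3b", 330, 140, 4.0, "centroparietal", "st_second_active")
  )
  if (condition == "passive") specs <- specs[specs$applies_to != "st_second_active", ]
  specs
}

# Per-channel gain in [0, 1]: Gaussian falloff of great-circle distance from a
# synthetic two-pole anchor (frontocentral ~ FCz, centroparietal ~ between CPz
# and Pz). Sensor-level stand-in, not a forward-model projection. Mastoids get
# zero gain (they carry noise only and act as the offline reference).
topography_gain <- function(montage, topography, width_rad = 0.9) {
  anchor <- switch(topography,
    frontocentral = montage$pos["FCz", ],
    centroparietal = {
      v <- montage$pos["CPz", ] + montage$pos["Pz", ]
      v / sqrt(sum(v^2))
    },
    stopf("unknown topography '%s'", topography))
  cosang <- pmin(1, pmax(-1, as.vector(montage$pos %*% anchor)))
  d <- acos(cosang)
  g <- exp(-0.5 * (d / width_rad)^2)
  g[montage$labels %in% montage$ref_labels] <- 0
  g <- g / max(g)
  setNames(g, montage$labels)
}

# Event rows of a schedule that a component applies to.
component_events <- function(schedule, applies_to, condition) {
  an <- schedule$analyzed | TRUE  # components are physiological: every event counts
  switch(applies_to,
    all_stimuli = schedule,
    deviant_second = schedule[schedule$position == "second" &
                                schedule$pair_type %in% c("SF", "ST"), ],
    st_second = schedule[schedule$position == "second" &
                           schedule$pair_type == "ST", ],
    st_second_active = if (identical(condition, "active"))
      schedule[schedule$position == "second" & schedule$pair_type == "ST", ]
    else schedule[0, ],
    stopf("unknown applies_to rule '%s'", applies_to))
}
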