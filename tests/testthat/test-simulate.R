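one_pair_schedule <- function() {
  generate_session(
    paradigm_config(n_total_pairs = 1, n_regularity_pairs = 0,
                    n_ss = 1, n_sf = 0, n_st = 0,
                    n_st_context_ss = 0, n_st_context_sf = 0),
    "passive", seed = 1)
}

silent_noise <- function() noise_spec(broadband_sd_uv = 0, alpha_amplitude_uv = 0)

test_that("a noise-free stimulus reproduces the component template sum exactly", {
  mon <- montage_ant64()
  comps <- build_default_components("passive")[1:3, ]   # P1 / N1 / P2
  comps$latency_jitter_sd_ms <- 0
  sch <- one_pair_schedule()
  rec <- simulate_recording(sch, comps, silent_noise(), mon, seed = 1)
  t_ms <- (seq_len(ncol(rec$data)) - 1)
  expected <- numeric(length(t_ms))
  for (i in seq_len(nrow(comps))) {
    g <- topography_gain(mon, comps$topography[i])
    gain_fz <- g["Fz"] - g["CPz"]     # recorded against the CPz online reference
    sds <- comps$half_width_ms[i] / 2.355
    for (on in sch$onset_ms) {
      contrib <- comps$amplitude_uv[i] * gain_fz *
        exp(-0.5 * ((t_ms - on - comps$peak_latency_ms[i]) / sds)^2)
      contrib[abs(t_ms - on - comps$peak_latency_ms[i]) > 3.5 * sds] <- 0
      expected <- expected + contrib
    }
  }
  # agreement up to the documented +/-3.5 SD support truncation of each pulse
  expect_lt(max(abs(rec$data["Fz", ] - expected)), 0.01)
  expect_equal(which.max(rec$data["Fz", ]), which.max(expected))
  expect_equal(max(rec$data["Fz", ]), max(expected), tolerance = 1e-6)
})

test_that("simulation is additive across component sets under a shared seed", {
  mon <- montage_ant64()
  comps <- build_default_components("passive")
  comps$latency_jitter_sd_ms <- 5
  sch <- generate_session(tiny_paradigm(), "passive", seed = 2)
  ab <- simulate_recording(sch, comps, noise_spec(), mon, seed = 11)
  a <- simulate_recording(sch, comps[comps$name %in% c("P1", "N1", "P2"), ],
                          noise_spec(), mon, seed = 11)
  b <- simulate_recording(sch, comps[comps$name %in% c("MMN", "P3a"), ],
                          noise_spec(), mon, seed = 11)
  noise_only <- simulate_recording(sch, comps[0, ], noise_spec(), mon, seed = 11)
  expect_lt(max(abs(ab$data - (a$data + b$data - noise_only$data))), 1e-8)
})

test_that("zero-amplitude components leave pure noise that averages away", {
  mon <- montage_ant64()
  comps <- build_default_components("passive")
  comps$amplitude_uv <- 0
  sch <- generate_session(tiny_paradigm(), "passive", seed = 3)
  rec <- simulate_recording(sch, comps, noise_spec(), mon, seed = 4)
  rec250 <- filter_chain(rec)
  eps <- extract_epochs(rec250, "P1N1P2")
  avg <- epochs_average(eps$A)
  n <- dim(eps$A$data)[1]
  fz <- match("Fz", eps$A$channels)
  sd_trial <- sd(eps$A$data[, fz, ])
  # evoked mean shrinks like SD/sqrt(n); allow 4x for the finite sample
  expect_lt(max(abs(avg["Fz", ])), 4 * sd_trial / sqrt(n))
})

test_that("background noise has the configured spectral slope", {
  mon <- montage_ant64()
  sch <- one_pair_schedule()
  comps <- build_default_components("passive")[0, ]
  for (expo in c(0.5, 1)) {
    ns <- noise_spec(one_over_f_exponent = expo, alpha_amplitude_uv = 0,
                     spatial_smoothing = 0)
    rec <- simulate_recording(sch, comps, ns, mon, seed = 6)
    x <- rec$data["Cz", ]
    sp <- stats::spec.pgram(stats::ts(x, frequency = 1000), spans = 21,
                            plot = FALSE, taper = 0.1)
    band <- sp$freq > 1 & sp$freq < 100
    slope <- unname(coef(lm(log(sp$spec[band]) ~ log(sp$freq[band])))[2])
    expect_lt(abs(-slope - expo), 0.3)
  }
})

test_that("noise-free topography ordering matches the configured gain map", {
  mon <- montage_ant64()
  comp <- component_spec("P3b", 330, 140, 4, "centroparietal",
                         "st_second_active", latency_jitter_sd_ms = 0)
  sch <- generate_session(tiny_paradigm(), "active", seed = 5)
  rec <- simulate_recording(sch, comp, silent_noise(), mon, seed = 1,
                            condition = "active")
  st_second <- sch[sch$pair_type == "ST" & sch$position == "second", ]
  i_peak <- round(st_second$onset_ms[1] + 330) + 1
  g <- topography_gain(mon, "centroparietal")
  amp <- rec$data[, i_peak]
  # against the CPz reference the recorded value is amp * (g - g[CPz]):
  # channel ordering is preserved
  expect_equal(order(amp), order(g - g["CPz"]))
})

test_that("the passive condition carries no P3b and conditions differ only there", {
  a <- build_default_components("active")
  p <- build_default_components("passive")
  expect_false("P3b" %in% p$name)
  expect_identical(a[a$name != "P3b", ], p)
  # simulate one S-T second stimulus noise-free in both conditions: the
  # difference is exactly the P3b template
  mon <- montage_ant64()
  a$latency_jitter_sd_ms <- 0; p$latency_jitter_sd_ms <- 0
  sch <- generate_session(tiny_paradigm(), "active", seed = 8)
  ra <- simulate_recording(sch, a, silent_noise(), mon, seed = 2, condition = "active")
  rp <- simulate_recording(sch, p, silent_noise(), mon, seed = 2, condition = "passive")
  d <- ra$data - rp$data
  expect_gt(max(abs(d)), 1)            # P3b present
  st_first <- sch[sch$pair_type != "ST" | sch$position == "first", ]
  i_pre <- round(st_first$onset_ms[1] + 100) + 1
  expect_lt(abs(d["Pz", i_pre]), 1e-9) # no difference away from S-T seconds
})

test_that("cohort simulation pairs sessions and respects the seed contract", {
  cfg <- tiny_paradigm()
  coh <- simulate_cohort(2, cfg, noise_spec(), between_subject_sd = 0,
                         seed = 21)
  expect_length(coh, 2)
  for (part in coh) {
    expect_identical(part$active$events$onset_ms, part$passive$events$onset_ms)
    expect_identical(part$active$events$stimulus_code,
                     part$passive$events$stimulus_code)
  }
  # between_subject_sd = 0: identical perturbations across participants
  expect_equal(coh[[1]]$perturbation$amp_factor,
               rep(1, nrow(coh[[1]]$perturbation)))
  coh2 <- simulate_cohort(2, cfg, noise_spec(), between_subject_sd = 0,
                          seed = 21)
  expect_identical(coh[[1]]$active$data, coh2[[1]]$active$data)
})
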