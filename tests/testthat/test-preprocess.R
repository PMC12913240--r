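make_raw <- function(data, mon = montage_ant64(), events = NULL, srate = 1000) {
  rownames(data) <- mon$labels
  structure(list(data = data, srate = srate, montage = mon,
                 events = events, reference = "CPz", condition = "passive"),
            class = c("lg_recording"))
}

test_that("the filter chain notches 50 Hz, removes DC and downsamples to 250 Hz", {
  mon <- montage_ant64()
  n <- 20000
  tt <- seq_len(n) / 1000
  X <- matrix(0, 64, n)
  X[which(mon$labels == "Cz"), ] <- 20 * sin(2 * pi * 50 * tt)   # mains
  X[which(mon$labels == "Fz"), ] <- 15                            # DC offset
  X[which(mon$labels == "Pz"), ] <- 10 * sin(2 * pi * 10 * tt)    # passband
  out <- filter_chain(make_raw(X, mon))
  expect_equal(out$srate, 250)
  expect_equal(ncol(out$data), ceiling(n / 4))
  mid <- 1000:4000   # avoid edge transients
  in_amp <- 20
  out_amp <- max(abs(out$data["Cz", mid]))
  expect_gt(20 * log10(in_amp / out_amp), 40)
  expect_lt(abs(mean(out$data["Fz", mid])), 0.1)
  # passband content survives largely unattenuated
  expect_gt(max(out$data["Pz", mid]), 8)
})

test_that("re-referencing requires mastoids and neutralizes their mean", {
  mon8 <- montage_subset(montage_ant64(), 8)
  X <- matrix(rnorm(8 * 4000), 8, 4000)
  expect_error(filter_chain(make_raw(X, mon8)), "M1/M2")
  mon <- montage_ant64()
  X <- matrix(rnorm(64 * 8000), 64, 8000)
  out <- filter_chain(make_raw(X, mon))
  expect_lt(max(abs(out$data["M1", ] + out$data["M2", ])), 1e-9)
})

test_that("epoch extraction realizes the published windows and counts", {
  cfg <- tiny_paradigm()
  sch <- generate_session(cfg, "passive", seed = 13)
  comps <- build_default_components("passive")
  rec <- filter_chain(simulate_recording(sch, comps, noise_spec(),
                                         montage_ant64(), seed = 13))
  lf <- extract_epochs(rec, "Local_SF")
  expect_equal(dim(lf$A$data)[1], cfg$n_sf)
  expect_equal(dim(lf$B$data)[1], cfg$n_sf)
  expect_length(lf$A$times, 113)
  expect_equal(range(lf$A$times), c(-100, 348))

  g1 <- extract_epochs(rec, "Global_SS_ST1")
  expect_equal(dim(g1$A$data)[1], cfg$n_st_context_ss)
  expect_length(g1$A$times, 225)
  expect_equal(range(g1$A$times), c(-100, 796))
  # control epochs come from the second stimulus of the preceding context pair
  g2 <- extract_epochs(rec, "Global_SF_ST2")
  expect_equal(dim(g2$A$data)[1], cfg$n_st_context_sf)
  expect_true(all(g2$B$label == "F"))

  p <- extract_epochs(rec, "P1N1P2")
  expect_equal(dim(p$A$data)[1], cfg$n_ss + cfg$n_sf + cfg$n_st)
  expect_equal(range(p$B$times), c(-448, 0))

  no_st <- paradigm_config(n_total_pairs = 40, n_regularity_pairs = 2,
                           n_ss = 20, n_sf = 18, n_st = 0,
                           n_st_context_ss = 0, n_st_context_sf = 0)
  rec0 <- filter_chain(simulate_recording(
    generate_session(no_st, "passive", seed = 1), comps, noise_spec(),
    montage_ant64(), seed = 1))
  expect_error(extract_epochs(rec0, "Global_SS_ST1"), "no qualifying")
})

test_that("baseline correction zeroes the baseline window to tolerance", {
  sch <- generate_session(tiny_paradigm(), "passive", seed = 17)
  rec <- filter_chain(simulate_recording(sch, build_default_components("passive"),
                                         noise_spec(), montage_ant64(), seed = 17))
  for (cn in c("P1N1P2", "Local_ST", "Global_SF_ST2")) {
    eps <- extract_epochs(rec, cn)
    for (side in c("A", "B")) {
      ep <- eps[[side]]
      spec <- contrast_spec(cn)
      bw <- if (side == "A") spec$baseline_a else spec$baseline_b
      bl <- which(ep$times >= bw[1] & ep$times <= bw[2])
      means <- apply(ep$data[, , bl, drop = FALSE], c(1, 2), mean)
      expect_lt(max(abs(means)) / max(abs(ep$data)), 1e-9)
    }
  }
})

test_that("a noise-free P1 peaks at its configured latency in the averaged epoch", {
  comps <- build_default_components("passive")[1, ]   # P1 only
  comps$latency_jitter_sd_ms <- 0
  sch <- generate_session(tiny_paradigm(), "passive", seed = 19)
  rec <- filter_chain(simulate_recording(
    sch, comps, noise_spec(broadband_sd_uv = 0, alpha_amplitude_uv = 0),
    montage_ant64(), seed = 19))
  eps <- extract_epochs(rec, "P1N1P2")
  avg <- epochs_average(eps$A)
  peak_t <- eps$A$times[which.max(avg["Fz", ])]
  expect_lte(abs(peak_t - 76), 4)   # one sample at 250 Hz
})

test_that("matched rejection keeps counts equal for random artifact placements", {
  set.seed(31)
  mk <- function() {
    d <- array(rnorm(40 * 4 * 20), c(40, 4, 20))
    epoch_set(d, seq(0, by = 4, length.out = 20),
              c("Fz", "Cz", "Pz", "M1"), ref_labels = "M1")
  }
  for (r in 1:20) {
    A <- mk(); B <- mk()
    A$data[sample(40, 5), 2, 3] <- 150
    B$data[sample(40, 5), 1, 7] <- -200
    out <- reject_amplitude(A, B, threshold_uv = 100, matched = TRUE)
    expect_equal(dim(out$A$data)[1], dim(out$B$data)[1])
    expect_true(max(abs(out$A$data[, 1:3, ])) <= 100)
  }
  # artifacts on the reference channel alone never reject
  A <- mk(); B <- mk()
  A$data[, 4, ] <- 500
  out <- reject_amplitude(A, B)
  expect_equal(dim(out$A$data)[1], 40)
  # degenerate threshold rejects everything
  expect_error(reject_amplitude(mk(), mk(), threshold_uv = 0), "every trial")
  # unmatched mode drops sides independently
  A <- mk(); B <- mk()
  A$data[1, 1, 1] <- 1000
  out <- reject_amplitude(A, B, matched = FALSE)
  expect_equal(dim(out$A$data)[1], 39)
  expect_equal(dim(out$B$data)[1], 40)
})
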