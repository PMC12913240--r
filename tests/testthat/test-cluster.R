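test_that("the paired t map matches hand computation and handles degeneracy", {
  mon <- montage_subset(montage_ant64(), 8)
  n_t <- 3
  A <- array(0, c(4, 8, n_t)); B <- array(0, c(4, 8, n_t))
  dimnames(A)[[2]] <- dimnames(B)[[2]] <- mon$labels
  # toy difference set {1, 2, 0, 1} at one cell: t = mean / (sd / sqrt(n))
  # = 1 / (sqrt(2/3) / 2) = sqrt(6)
  A[, 1, 1] <- c(1, 2, 0, 1)
  A[, 2, 2] <- c(1, 1, 1, 1)   # zero variance, nonzero mean -> capped
  g <- group_data(A, B, c(0, 4, 8), mon)
  expect_warning(tm <- paired_t_map(g), "zero-variance")
  expect_equal(unname(tm[1, 1]), sqrt(6), tolerance = 1e-12)
  expect_equal(unname(tm[2, 2]), 1e4)
  expect_equal(unname(tm[3, 3]), 0)     # zero variance, zero mean

  gid <- group_data(A, A, c(0, 4, 8), mon)
  expect_warning(tm0 <- paired_t_map(gid))
  expect_true(all(tm0 == 0))
})

test_that("TFCE equals the brute-force oracle and is monotone under scaling", {
  adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  m <- rbind(c(2, 2, 0), c(2, 0, 0))
  # hand value: both thresholds h = 1, 2 give the 3-point component:
  # sqrt(3) * (1 + 4) = 8.6602540
  out <- tfce(m, adj, dh = 1)
  expect_equal(out[1, 1], sqrt(3) * 5, tolerance = 1e-12)
  expect_equal(out, tfce_oracle(m, adj), ignore_attr = TRUE)

  expect_true(all(tfce(matrix(0, 2, 3), adj, n_steps = 10) == 0))

  set.seed(4)
  for (r in 1:25) {
    mm <- matrix(sample(-3:3, 8, replace = TRUE), 2, 4)
    expect_equal(tfce(mm, adj, dh = 1), tfce_oracle(mm, adj),
                 ignore_attr = TRUE)
    scaled <- tfce(2 * mm, adj, dh = 1)
    base <- tfce(mm, adj, dh = 1)
    expect_true(all(abs(scaled) >= abs(base) - 1e-12))
    expect_true(all(sign(scaled) == sign(base) | base == 0))
  }
})

test_that("sign symmetry: negating the data flips polarity, keeps p-values", {
  g <- small_group(6, effect = {
    e <- matrix(0, 8, 25); e[1:3, 8:14] <- 3; e
  }, seed = 2)
  res_pos <- permutation_test(g, n_perm = 200, seed = 9, hat = 0.05)
  g_neg <- g; g_neg$A <- g$B; g_neg$B <- g$A
  res_neg <- permutation_test(g_neg, n_perm = 200, seed = 9, hat = 0.05)
  expect_equal(nrow(res_pos), nrow(res_neg))
  if (nrow(res_pos)) {
    expect_equal(res_pos$p_value, res_neg$p_value)
    expect_equal(abs(res_pos$peak_stat), abs(res_neg$peak_stat))
    expect_true(all(res_pos$polarity != res_neg$polarity))
  }
  expect_gt(nrow(res_pos), 0)   # the injected effect is found at all
})

test_that("reported clusters satisfy the duration and adjacency criteria", {
  n_found <- 0
  for (seed in 1:5) {
    g <- small_group(6, effect = {
      e <- matrix(0, 8, 25)
      e[sample(1:8, 3), sample(1:18, 1) + 0:6] <- 3
      e
    }, seed = seed)
    res <- permutation_test(g, n_perm = 150, seed = seed, hat = 0.05)
    if (nrow(res)) {
      n_found <- n_found + 1
      expect_true(all(res$offset_ms - res$onset_ms >= 20))
      expect_true(all(res$p_value >= 0 & res$p_value <= 1))
    }
  }
  expect_gt(n_found, 0)
})

test_that("an injected deflection is recovered with its latency at Fz", {
  mon <- montage_subset(montage_ant64(), 8)
  n_t <- 75                                 # 0..296 ms at 250 Hz
  times <- seq(0, by = 4, length.out = n_t)
  # smooth positive deflection peaking at 184 ms, strongest at Fz
  bump <- 3 * exp(-0.5 * ((times - 184) / 25)^2)
  dfz <- acos(pmin(1, pmax(-1, as.vector(mon$pos %*% mon$pos["Fz", ]))))
  gain <- setNames(exp(-0.5 * (dfz / 1.5)^2), mon$labels)
  eff <- gain %o% bump
  set.seed(5)
  # per-participant amplitude scaling: across-participant variance tracks
  # the effect, as in real evoked data
  amp_p <- 1 + rnorm(8, sd = 0.25)
  A <- array(rnorm(8 * 8 * n_t, sd = 0.4), c(8, 8, n_t)) + amp_p %o% eff
  B <- array(rnorm(8 * 8 * n_t, sd = 0.4), c(8, 8, n_t))
  dimnames(A)[[2]] <- dimnames(B)[[2]] <- mon$labels
  g <- group_data(A, B, times, mon)
  res <- permutation_test(g, n_perm = 200, seed = 3, hat = 0.05)
  expect_gt(nrow(res), 0)
  top <- res[which.max(abs(res$peak_stat)), ]
  expect_true(top$onset_ms <= 184 && top$offset_ms >= 184)

  rep_fz <- report_representative(res, "Fz")
  fz_top <- rep_fz[rep_fz$cluster == which.max(abs(res$peak_stat)), ]
  expect_true(fz_top$present)
  expect_lt(abs(fz_top$peak_latency_ms - 184), 30)
  # restriction contract: the channel report stays inside the cluster bounds
  ok <- rep_fz$present
  expect_true(all(rep_fz$onset_ms[ok] >= res$onset_ms[ok] - 1e-9))
  expect_true(all(rep_fz$offset_ms[ok] <= res$offset_ms[ok] + 1e-9))
  expect_error(report_representative(res, "Nope"), "not in result")
})

test_that("clusters absent at a channel are flagged as such", {
  mon <- montage_subset(montage_ant64(), 8)
  n_t <- 25
  # effect confined to occipital channels, far from Fz
  eff <- matrix(0, 8, n_t)
  eff[match(c("P3", "P4", "Oz"), mon$labels), 10:18] <- 4
  set.seed(6)
  A <- array(rnorm(6 * 8 * n_t, sd = 0.3), c(6, 8, n_t)) + rep(1, 6) %o% eff
  B <- array(rnorm(6 * 8 * n_t, sd = 0.3), c(6, 8, n_t))
  dimnames(A)[[2]] <- dimnames(B)[[2]] <- mon$labels
  g <- group_data(A, B, seq(0, by = 4, length.out = n_t), mon)
  res <- permutation_test(g, n_perm = 200, seed = 2, hat = 0.05)
  expect_gt(nrow(res), 0)
  rep_fz <- report_representative(res, "Fz")
  expect_true(any(!rep_fz$present))
})

test_that("exhaustive and sampled nulls agree and determinism holds", {
  g <- small_group(5, effect = {
    e <- matrix(0, 8, 25); e[2:4, 5:15] <- 1.5; e
  }, seed = 8)
  r1 <- permutation_test(g, n_perm = 200, seed = 4)          # auto: 2^5 = 32
  r2 <- permutation_test(g, n_perm = 200, seed = 99)
  expect_identical(tidy(r1), tidy(r2))   # exhaustive null ignores the seed
  r3 <- permutation_test(g, n_perm = 400, seed = 4, method = "monte-carlo")
  r4 <- permutation_test(g, n_perm = 400, seed = 4, method = "monte-carlo")
  expect_identical(tidy(r3), tidy(r4))
})
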