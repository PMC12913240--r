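toy_epochs <- function(n_trials, n_ch = 3, n_t = 10, offset = 0, sd = 1,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- array(rnorm(n_trials * n_ch * n_t, mean = offset, sd = sd),
             c(n_trials, n_ch, n_t))
  epoch_set(d, seq(0, by = 4, length.out = n_t),
            paste0("ch", seq_len(n_ch)))
}

test_that("block averaging partitions in temporal order and drops remainders", {
  ep <- toy_epochs(200, seed = 1)
  b <- block_average(ep, 50)
  expect_equal(dim(b$data)[1], 50)
  expect_equal(b$data[1, , ], apply(ep$data[1:4, , ], c(2, 3), mean))
  expect_equal(b$data[50, , ], apply(ep$data[197:200, , ], c(2, 3), mean))

  # 50 trials -> blocks of 1, order preserved
  ep50 <- toy_epochs(50, seed = 2)
  b50 <- block_average(ep50, 50)
  expect_equal(b50$data, ep50$data)

  # 237 trials -> blocks of 4, last 37 dropped; grand mean oracle
  ep237 <- toy_epochs(237, seed = 3)
  b237 <- block_average(ep237, 50)
  expect_equal(dim(b237$data)[1], 50)
  expect_equal(mean(b237$data), mean(ep237$data[1:200, , ]), tolerance = 1e-12)

  expect_warning(block_average(toy_epochs(30), 50), "single-trial")
})

test_that("window cropping keeps the documented sample counts", {
  ep <- epoch_set(array(0, c(2, 3, 113)), seq(-100, by = 4, length.out = 113),
                  paste0("c", 1:3))
  expect_equal(dim(crop_to_window(ep, c(0, 300))$data)[3], 75)
  expect_equal(dim(crop_to_window(ep, range(ep$times) + c(0, 4))$data)[3], 113)
  epg <- epoch_set(array(0, c(2, 3, 225)), seq(-100, by = 4, length.out = 225),
                   paste0("c", 1:3))
  expect_equal(dim(crop_to_window(epg, c(0, 400))$data)[3], 100)
  expect_error(crop_to_window(ep, c(900, 1000)), "no samples")
})

test_that("the Gram-Cholesky SVM path equals the direct high-dimensional fit", {
  set.seed(11)
  n <- 30; d <- 400
  X <- matrix(rnorm(n * d), n, d)
  X[1:(n / 2), ] <- X[1:(n / 2), ] + 0.4
  y <- factor(rep(c("A", "B"), each = n / 2))
  for (r in 1:5) {
    tr <- sort(sample(n, 24)); te <- setdiff(1:n, tr)
    mu <- colMeans(X[tr, ]); sg <- apply(X[tr, ], 2, sd); sg[sg < 1e-12] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    direct <- predict(e1071::svm(Xs[tr, ], y[tr], kernel = "linear",
                                 scale = FALSE), Xs[te, ])
    G <- tcrossprod(Xs)
    Z <- t(chol(G + diag(1e-9 * max(diag(G)), n)))
    via_gram <- predict(e1071::svm(Z[tr, ], y[tr], kernel = "linear",
                                   scale = FALSE), Z[te, ])
    expect_identical(as.character(direct), as.character(via_gram))
  }
})

test_that("sensitivity detects separable classes and not identical ones", {
  set.seed(21)
  A <- matrix(rnorm(20 * 50), 20, 50) + 3
  B <- matrix(rnorm(20 * 50), 20, 50)
  r <- evaluate_sensitivity(A, B, n_iter = 50, seed = 1)
  expect_gt(r$mean_accuracy, 0.95)
  expect_true(r$detected)
  expect_lt(r$p_value, 0.05)

  # two samples of one distribution: chance-level accuracy
  C1 <- matrix(rnorm(20 * 50), 20, 50)
  C2 <- matrix(rnorm(20 * 50), 20, 50)
  r0 <- evaluate_sensitivity(C1, C2, n_iter = 50, seed = 2)
  se <- sd(r0$true_accuracies)
  expect_lt(abs(r0$mean_accuracy - 0.5), 4 * max(se, 0.05))

  expect_error(evaluate_sensitivity(A[1:10, ], B, n_iter = 5), "imbalance")
  expect_error(evaluate_sensitivity(A[1:3, ], B[1:3, ], n_iter = 5),
               "at least k")
  # distributions have the configured length and range
  expect_length(r$true_accuracies, 50)
  expect_length(r$null_accuracies, 50)
  expect_true(all(r$true_accuracies >= 0 & r$true_accuracies <= 1))
})

test_that("accuracy is monotone in effect size and improves with blocking", {
  amps <- c(0, 0.2, 0.5, 1.5)
  accs <- sapply(seq_along(amps), function(i) {
    set.seed(100 + i)
    sig <- matrix(rnorm(60), 1, 60)
    A <- matrix(rnorm(24 * 60), 24, 60) + rep(1, 24) %o% (amps[i] * sig[1, ])
    B <- matrix(rnorm(24 * 60), 24, 60)
    r <- evaluate_sensitivity(A, B, n_iter = 30, seed = 5)
    c(r$mean_accuracy, sd(r$true_accuracies))
  })
  tol <- apply(rbind(accs[2, -1], accs[2, -4]), 2, max)
  expect_true(all(diff(accs[1, ]) >= -tol))
  expect_gt(accs[1, 4], accs[1, 1])

  # block averaging raises accuracy over single trials at matched trial count
  set.seed(77)
  sig <- rnorm(30)
  mk <- function(n) {
    d <- array(rnorm(n * 3 * 10, sd = 2), c(n, 3, 10))
    d <- d + rep(1, n) %o% array(sig, c(3, 10))
    epoch_set(d, seq(0, by = 4, length.out = 10), paste0("c", 1:3))
  }
  A <- mk(100); B <- {
    d <- array(rnorm(100 * 3 * 10, sd = 2), c(100, 3, 10))
    epoch_set(d, seq(0, by = 4, length.out = 10), paste0("c", 1:3))
  }
  feat <- function(ep) epochs_features(ep)
  blocked <- evaluate_sensitivity(feat(block_average(A, 20)),
                                  feat(block_average(B, 20)),
                                  n_iter = 30, seed = 6)
  single <- evaluate_sensitivity(feat(A)[1:20, ], feat(B)[1:20, ],
                                 n_iter = 30, seed = 6)
  expect_gte(blocked$mean_accuracy,
             single$mean_accuracy - sd(single$true_accuracies))
})

test_that("the active-passive comparison responds only to a real difference", {
  set.seed(55)
  base <- function() toy_epochs(40, n_ch = 4, n_t = 20)
  spec <- contrast_spec("Global_SS_ST1")
  spec$decode_window_ms <- c(0, 80)
  # no condition difference
  r0 <- active_passive_contrast(base(), base(), contrast = spec,
                                n_blocks = 20, n_iter = 40, seed = 1)
  expect_lt(r0$mean_accuracy, r0$threshold + 0.15)
  # strong P3b-like difference in the active session only
  act <- base(); act$data <- act$data + 2
  r1 <- active_passive_contrast(act, base(), contrast = spec,
                                n_blocks = 20, n_iter = 40, seed = 2)
  expect_true(r1$detected)
  expect_match(r1$contrast, "active vs passive")
})
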