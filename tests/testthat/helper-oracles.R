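# Independent oracles and small fixture builders shared across tests.

# Brute-force TFCE: plain-R breadth-first search over the spatiotemporal
# grid, summing extent^E * h^H * dh across explicit thresholds. Kept naive on
# purpose — it is the reference the fast implementation is checked against.
tfce_oracle <- function(map, adj_mat, E = 0.5, H = 2, dh = 1) {
  n_ch <- nrow(map); n_t <- ncol(map)
  out <- matrix(0, n_ch, n_t)
  for (sgn in c(1, -1)) {
    vals <- sgn * map
    mx <- max(vals)
    if (mx <= 0) next
    for (h in seq(dh, mx, by = dh)) {
      supra <- vals >= h
      seen <- matrix(FALSE, n_ch, n_t)
      for (c0 in seq_len(n_ch)) for (t0 in seq_len(n_t)) {
        if (!supra[c0, t0] || seen[c0, t0]) next
        comp <- list(c(c0, t0)); seen[c0, t0] <- TRUE; q <- list(c(c0, t0))
        while (length(q)) {
          v <- q[[1]]; q <- q[-1]
          nbrs <- list()
          if (v[2] > 1) nbrs <- c(nbrs, list(c(v[1], v[2] - 1)))
          if (v[2] < n_t) nbrs <- c(nbrs, list(c(v[1], v[2] + 1)))
          for (u in which(adj_mat[v[1], ])) nbrs <- c(nbrs, list(c(u, v[2])))
          for (u in nbrs) if (supra[u[1], u[2]] && !seen[u[1], u[2]]) {
            seen[u[1], u[2]] <- TRUE
            q <- c(q, list(u)); comp <- c(comp, list(u))
          }
        }
        inc <- length(comp)^E * h^H * dh
        for (u in comp) out[u[1], u[2]] <- out[u[1], u[2]] + sgn * inc
      }
    }
  }
  out
}

# Exhaustive sign-flip null at small n: every one of the 2^n sign patterns,
# max |TFCE| each, p = fraction of patterns whose max reaches the observed.
exhaustive_signflip_p <- function(A, B, montage, channels, n_steps = 50) {
  n <- dim(A)[1]
  D <- A - B
  adj <- montage$adjacency[channels, channels]
  t_map <- function(signs) {
    Ds <- D * array(rep(signs, prod(dim(D)[2:3])), dim(D))
    m <- apply(Ds, c(2, 3), mean)
    s <- apply(Ds, c(2, 3), sd)
    tt <- m / (s / sqrt(n))
    tt[!is.finite(tt)] <- 0
    tt
  }
  max_tfce <- function(signs) {
    tm <- t_map(signs)
    mx <- max(abs(tm))
    if (mx == 0) return(0)
    max(abs(tfce(tm, adj, dh = mx / n_steps)))
  }
  obs <- max_tfce(rep(1, n))
  signs_all <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  nulls <- apply(signs_all, 1, max_tfce)
  mean(nulls >= obs - 1e-12)
}

# Small montage + group-data builder for cluster tests.
small_group <- function(n_participants, n_ch = 8, n_t = 25, seed = 1,
                        effect = NULL) {
  mon <- montage_subset(montage_ant64(), n_ch)
  set.seed(seed)
  A <- array(rnorm(n_participants * n_ch * n_t), c(n_participants, n_ch, n_t))
  B <- array(rnorm(n_participants * n_ch * n_t), c(n_participants, n_ch, n_t))
  if (!is.null(effect)) A <- A + rep(1, n_participants) %o% effect
  dimnames(A)[[2]] <- dimnames(B)[[2]] <- mon$labels
  group_data(A, B, seq(0, by = 4, length.out = n_t), mon)
}

# Tiny paradigm usable in seconds.
tiny_paradigm <- function(...) {
  paradigm_config(n_total_pairs = 64, n_regularity_pairs = 4,
                  n_ss = 25, n_sf = 23, n_st = 12,
                  n_st_context_ss = 6, n_st_context_sf = 6, ...)
}

expect_no_violations <- function(schedule, config = attr(schedule, "config")) {
  v <- validate_schedule(schedule, config)
  expect_equal(nrow(v), 0, info = paste(utils::capture.output(print(v)), collapse = "\n"))
}
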