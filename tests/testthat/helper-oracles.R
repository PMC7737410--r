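# Independent oracles and small fixture builders shared across tests.

# Amari index of P = W_unmixing %*% A_true: 0 iff P is a scaled permutation.
amari_index <- function(P) {
  p <- abs(P)
  n <- nrow(p)
  r <- sum(rowSums(p) / apply(p, 1, max) - 1)
  c <- sum(colSums(p) / apply(p, 2, max) - 1)
  (r + c) / (2 * n * (n - 1))
}

# Exhaustive greedy average-linkage agglomeration: repeatedly merge the pair
# of clusters with the highest average similarity while it strictly exceeds
# the threshold; lowest-index pair wins ties. Independent of hclust.
brute_upgma <- function(sp, threshold = 0.75) {
  n <- nrow(sp)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- NULL
    best_sim <- -Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        s <- mean(sp[clusters[[i]], clusters[[j]]])
        if (s > best_sim + 1e-12) {
          best_sim <- s
          best <- c(i, j)
        }
      }
    }
    if (best_sim <= threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(n)
  for (ci in seq_along(clusters)) assign[clusters[[ci]]] <- ci
  assign
}

# Two cluster labelings are equivalent up to renaming.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Planted non-negative envelope matrix with K equal-energy components on
# disjoint signal supports: the best rank-(K-1) approximation can capture at
# most (K-1)/K of the energy, so VAF crosses 0.9 exactly at rank K.
planted_envelopes <- function(K, m = 240, n = 24, noise = 0.01, seed = 1) {
  emgsynergy:::with_seed(seed, {
    supp <- split(seq_len(n), rep(seq_len(K), length.out = n))
    M <- matrix(0, K, n)
    T0 <- matrix(0, m, K)
    tt <- seq_len(m) / m
    for (k in seq_len(K)) {
      M[k, supp[[k]]] <- stats::runif(length(supp[[k]]), 0.5, 1.5)
      T0[, k] <- pmax(0, sin(2 * pi * tt * 3 + 2 * pi * k / K))^2 + 0.05
      T0[, k] <- T0[, k] / (sqrt(sum(T0[, k]^2)) * sqrt(sum(M[k, ]^2)))
    }
    E <- T0 %*% M
    if (noise > 0) {
      E <- E + noise * stats::sd(E) * matrix(abs(stats::rnorm(m * n)), m)
    }
    list(E = E, T0 = T0, M0 = M)
  })
}

# Small cached simulated dataset reused by several module tests.
.test_cache <- new.env(parent = emptyenv())
tiny_sim <- function(noise = TRUE) {
  key <- if (noise) "noisy" else "clean"
  if (is.null(.test_cache[[key]])) {
    cfg <- sim_config(fs_emg = 512, trial_duration_s = 1, gap_s = 0.3,
                      n_reps = 2, onset_latency_s = 0.4, ramp_s = 0.1,
                      cursor_ramp_s = 0.5, seed = 42,
                      snr_db = if (noise) 10 else Inf,
                      line_amp = if (noise) 0.05 else 0,
                      baseline_amp = if (noise) 0.2 else 0)
    .test_cache[[key]] <- simulate_dataset(cfg)
  }
  .test_cache[[key]]
}

# Toy trial set for classifier tests: optional direction-dependent channel
# pattern on top of unit noise.
fake_trialset <- function(n_per_cell = 5, C = 5, seed = 1, signal = 1) {
  emgsynergy:::with_seed(seed, {
    n <- n_per_cell * 16
    labels <- data.frame(
      direction = rep(rep(1:8, each = n_per_cell), 2),
      posture = rep(c(0, 90), each = 8 * n_per_cell)
    )
    X <- array(stats::rnorm(n * C * 25), c(n, C, 25))
    if (signal > 0) {
      bump <- sin(seq(0, pi, length.out = 25))
      for (i in seq_len(n)) {
        d <- labels$direction[i]
        ch <- (d - 1) %% C + 1
        X[i, ch, ] <- X[i, ch, ] + 3 * signal * bump
        X[i, , ] <- X[i, , ] + signal * cos(2 * pi * d / 8)
      }
    }
    structure(list(data = X, labels = labels, frame = "extrinsic", fs = 50,
                   input_type = "toy"),
              class = "trial_set")
  })
}
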