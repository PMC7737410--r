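# Non-negative muscle-synergy factorization E = T M by hierarchical
# alternating least squares (HALS): pseudo-joint-torque envelopes, the HALS
# solver, the uncentered VAF criterion, and the dual-condition synergy-count
# selection (VAF > 0.9 and plateau-linearity MSE < 1e-4).

#' Convert signals to pseudo-joint-torque envelopes
#'
#' Per signal: divide by its mean rectified amplitude over the whole
#' dataset, rectify, low-pass with a zero-phase 2nd-order Butterworth at
#' 5 Hz, and clip residual negative filter ringing to zero. A constant
#' signal maps to the constant 1.
#'
#' @param signals Signals x samples matrix (EMG channels or ICs).
#' @param fs Sampling rate in Hz (> 10).
#' @return List of class `envelope_matrix`: `E` (time x signals,
#'   non-negative), `fs`, `norms` (per-signal normalization constants).
#' @export
to_pseudo_torque <- function(signals, fs) {
  stopifnot(is.matrix(signals), fs > 10)
  norms <- apply(signals, 1, function(x) mean(abs(x)))
  if (any(norms <= 0)) {
    stop("cannot normalize: signal(s) with zero mean rectified amplitude: ",
         paste(which(norms <= 0), collapse = ", "))
  }
  bf <- signal::butter(2, 5 / (fs / 2), type = "low")
  E <- apply(signals / norms, 1, function(x) {
    pmax(zp_filter(bf, abs(x)), 0)
  })
  structure(list(E = E, fs = fs, norms = norms), class = "envelope_matrix")
}

#' HALS non-negative matrix factorization
#'
#' Factorizes a non-negative matrix `E` (time x signals) as `T M` with
#' `T >= 0` (time x rank activations) and `M >= 0` (rank x signals synergy
#' vectors), minimizing the Frobenius reconstruction error by columnwise /
#' rowwise HALS updates. The objective is non-increasing across iterations.
#' Rows of `M` are scaled to unit maximum with the scale absorbed into `T`.
#'
#' @param E Non-negative time x signals matrix.
#' @param rank Number of synergies `s`, `1 <= s <= min(dim(E))`.
#' @param seed Seed for the non-negative uniform initialization.
#' @param max_iter Maximum HALS sweeps (default 500).
#' @param tol Relative objective-change stopping tolerance (default 1e-8).
#' @param init Optional list(T, M) warm start (overrides the seeded init).
#' @return List of class `synergy_set`: `T`, `M`, `rank`, `vaf`,
#'   `objective_trace`, `converged`, `iterations`.
#' @export
hals_nmf <- function(E, rank, seed = 1, max_iter = 500, tol = 1e-8,
                     init = NULL) {
  stopifnot(is.matrix(E))
  if (min(E) < 0) stop("E must be non-negative")
  m <- nrow(E); n <- ncol(E)
  if (rank < 1 || rank > min(m, n)) stop("rank out of range [1, min(dim(E))]")
  eps <- 1e-12
  if (is.null(init)) {
    sc <- sqrt(mean(E) / rank)
    ini <- with_seed(seed, list(
      T_ = matrix(stats::runif(m * rank), m) * sc,
      M = matrix(stats::runif(rank * n), rank) * sc
    ))
    T_ <- ini$T_; M <- ini$M
  } else {
    T_ <- init$T; M <- init$M
    stopifnot(nrow(T_) == m, ncol(T_) == rank, nrow(M) == rank, ncol(M) == n)
  }
  sstot <- sum(E^2)
  trace <- numeric(0)
  reinit_used <- rep(FALSE, rank)
  obj_prev <- Inf
  converged <- FALSE
  it_done <- 0
  for (it in seq_len(max_iter)) {
    # update T columns
    EMt <- E %*% t(M)          # m x s
    MMt <- tcrossprod(M)       # s x s
    for (j in seq_len(rank)) {
      T_[, j] <- pmax(T_[, j] + (EMt[, j] - T_ %*% MMt[, j]) /
                        (MMt[j, j] + eps), 0)
    }
    # update M rows
    TtE <- crossprod(T_, E)    # s x n
    TtT <- crossprod(T_)       # s x s
    for (j in seq_len(rank)) {
      M[j, ] <- pmax(M[j, ] + (TtE[j, ] - TtT[j, ] %*% M) /
                       (TtT[j, j] + eps), 0)
      if (all(M[j, ] == 0) && !reinit_used[j]) {
        # dead synergy: one random re-initialization, then allowed to die;
        # zeroing the activation column keeps the objective unchanged, so
        # the HALS trace stays non-increasing
        M[j, ] <- with_seed(seed + 7919L + j,
                            stats::runif(n) * sqrt(mean(E) / rank))
        T_[, j] <- 0
        reinit_used[j] <- TRUE
      }
    }
    # objective from the cached cross products (T unchanged by the M sweep)
    obj <- sstot - 2 * sum(M * TtE) + sum(TtT * tcrossprod(M))
    trace <- c(trace, obj)
    it_done <- it
    if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(obj_prev, eps)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  # unit-maximum synergy rows, scale absorbed into activations
  sc <- apply(M, 1, max)
  sc[sc <= 0] <- 1
  M <- M / sc
  T_ <- T_ * rep(sc, each = m)
  structure(
    list(T = T_, M = M, rank = rank, vaf = vaf(E, T_, M),
         objective_trace = trace, converged = converged,
         iterations = it_done, seed = seed),
    class = "synergy_set"
  )
}

#' Variance Accounted For of a factorization
#'
#' Uncentered VAF: `1 - ||E - T M||_F^2 / ||E||_F^2`. Set
#' `per_signal = TRUE` for the per-column variant (returned as a vector).
#'
#' @param E Data matrix; `T_`, `M` factor matrices.
#' @param per_signal Compute VAF per signal column instead of globally.
#' @return Scalar in `[0, 1]` (or vector if `per_signal`).
#' @export
vaf <- function(E, T_, M, per_signal = FALSE) {
  sst <- if (per_signal) colSums(E^2) else sum(E^2)
  if (any(sst == 0)) stop("zero-norm signal: VAF undefined")
  R <- E - T_ %*% M
  sse <- if (per_signal) colSums(R^2) else sum(R^2)
  1 - sse / sst
}

# Best-of-seeds HALS at one rank, optionally warm-started from the previous
# rank's solution padded with a near-zero extra synergy (this guarantees a
# non-decreasing best-VAF curve).
hals_best <- function(E, rank, seeds, max_iter, tol, warm = NULL) {
  fits <- lapply(seeds, function(sd) {
    hals_nmf(E, rank, seed = sd, max_iter = max_iter, tol = tol)
  })
  if (!is.null(warm) && warm$rank == rank - 1) {
    init <- list(
      T = cbind(warm$T, rep(1e-8, nrow(warm$T))),
      M = rbind(warm$M, rep(1e-8, ncol(warm$M)))
    )
    fits <- c(fits, list(hals_nmf(E, rank, seed = seeds[1], max_iter = max_iter,
                                  tol = tol, init = init)))
  }
  objs <- vapply(fits, function(f) utils::tail(f$objective_trace, 1), numeric(1))
  fits[[which.min(objs)]]
}

#' Select the synergy count from the VAF curve
#'
#' For each candidate rank the best factorization over `n_seeds` seeded
#' restarts (plus a warm start from the previous rank) gives the VAF curve.
#' The selected rank is the smallest `s` satisfying both conditions:
#' VAF(s) > `vaf_min` and the mean squared error of an ordinary
#' least-squares line fitted to the VAF curve over ranks `>= s` below
#' `slope_mse_max` (the curve has reached its linear plateau).
#'
#' @param E Non-negative envelope matrix (time x signals).
#' @param s_min,s_max Candidate rank range.
#' @param seed Base seed; restart seeds are derived from it.
#' @param n_seeds Restarts per rank (default 3).
#' @param vaf_min VAF threshold (default 0.9).
#' @param slope_mse_max Plateau-linearity threshold (default 1e-4).
#' @param max_iter,tol Passed to [hals_nmf()].
#' @return List: `selected_rank`, `vaf_curve` (named by rank),
#'   `slope_mse_curve`, `fits` (per-rank best `synergy_set`), `best_fit`.
#' @export
select_rank <- function(E, s_min = 3, s_max = 15, seed = 1, n_seeds = 3,
                        vaf_min = 0.9, slope_mse_max = 1e-4,
                        max_iter = 300, tol = 1e-7) {
  stopifnot(s_min >= 1, s_max <= min(dim(E)), s_min <= s_max)
  ranks <- s_min:s_max
  seeds <- seed + seq_len(n_seeds) - 1
  fits <- vector("list", length(ranks))
  warm <- NULL
  for (k in seq_along(ranks)) {
    fits[[k]] <- hals_best(E, ranks[k], seeds, max_iter, tol, warm = warm)
    warm <- fits[[k]]
  }
  vaf_curve <- vapply(fits, function(f) f$vaf, numeric(1))
  names(vaf_curve) <- ranks
  slope_mse <- vapply(seq_along(ranks), function(k) {
    y <- vaf_curve[k:length(ranks)]
    x <- ranks[k:length(ranks)]
    if (length(y) < 3) return(0)  # a line fits <= 2 points exactly
    fit <- stats::lm.fit(cbind(1, x), y)
    mean(fit$residuals^2)
  }, numeric(1))
  names(slope_mse) <- ranks
  ok <- vaf_curve > vaf_min & slope_mse < slope_mse_max
  if (!any(ok)) {
    why <- vapply(seq_along(ranks), function(k) {
      sprintf("s=%d: VAF=%.4f%s, slopeMSE=%.2e%s", ranks[k], vaf_curve[k],
              if (vaf_curve[k] <= vaf_min) " (fails VAF)" else "",
              slope_mse[k],
              if (slope_mse[k] >= slope_mse_max) " (fails linearity)" else "")
    }, character(1))
    stop("no synergy count satisfies both selection conditions:\n",
         paste(why, collapse = "\n"))
  }
  sel <- ranks[which(ok)[1]]
  list(selected_rank = sel, vaf_curve = vaf_curve,
       slope_mse_curve = slope_mse, fits = fits,
       best_fit = fits[[which(ranks == sel)]])
}
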