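# Synergy-module analysis across elbow postures: scalar-product similarity,
# UPGMA clustering into modules, cosine-tuning preferred directions and
# tuning weights, PD consistency within modules, and parallel/local module
# typing on the electrode grid.

#' Scalar product between two non-negative synergy vectors
#'
#' Normalized inner product `e_i . e_j / (||e_i|| ||e_j||)`; for
#' non-negative vectors it lies in `[0, 1]`.
#'
#' @param e_i,e_j Non-negative vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
scalar_product <- function(e_i, e_j) {
  stopifnot(length(e_i) == length(e_j))
  if (any(e_i < 0) || any(e_j < 0)) stop("synergy vectors must be non-negative")
  ni <- sqrt(sum(e_i^2)); nj <- sqrt(sum(e_j^2))
  if (ni == 0 || nj == 0) stop("zero synergy vector")
  sum(e_i * e_j) / (ni * nj)
}

#' Cluster synergies into modules by UPGMA
#'
#' Average-linkage (UPGMA) agglomeration on the dissimilarity `1 - SP`,
#' cut so that merges occur only while the average inter-cluster scalar
#' product exceeds the threshold (strictly).
#'
#' @param sp_matrix Symmetric similarity matrix with unit diagonal.
#' @param threshold Scalar-product threshold (default 0.75).
#' @return Integer module assignments (one per item).
#' @export
upgma_cluster <- function(sp_matrix, threshold = 0.75) {
  stopifnot(is.matrix(sp_matrix), nrow(sp_matrix) == ncol(sp_matrix))
  if (max(abs(sp_matrix - t(sp_matrix))) > 1e-8) {
    stop("similarity matrix must be symmetric")
  }
  n <- nrow(sp_matrix)
  if (n == 1) return(1L)
  d <- stats::as.dist(1 - sp_matrix)
  hc <- stats::hclust(d, method = "average")
  # strict SP > threshold: cut just below height 1 - threshold
  as.integer(stats::cutree(hc, h = (1 - threshold) - 1e-9))
}

#' Factorize one posture condition at a fixed synergy count
#'
#' Runs the HALS factorization on the envelope rows belonging to a
#' condition (Elbow 0, Elbow 90, or the total dataset) at the rank selected
#' on the total dataset, so posture-dependent synergies are comparable.
#'
#' @param E Envelope matrix (time x signals).
#' @param posture_per_row Posture (0/90, `NA` for inter-trial samples) for
#'   each row of `E`.
#' @param condition `"Total"`, `"Elbow0"` or `"Elbow90"`.
#' @param rank Synergy count (the Total-dataset selected rank).
#' @param seed Base seed. @param n_seeds Restarts (best objective kept).
#' @param max_iter,tol Passed to [hals_nmf()].
#' @return A `synergy_set` for the condition's rows.
#' @export
condition_synergies <- function(E, posture_per_row,
                                condition = c("Total", "Elbow0", "Elbow90"),
                                rank, seed = 1, n_seeds = 3,
                                max_iter = 300, tol = 1e-7) {
  condition <- match.arg(condition)
  stopifnot(length(posture_per_row) == nrow(E))
  rows <- switch(condition,
    Total = seq_len(nrow(E)),  # full timeline, so activations align with it
    Elbow0 = which(posture_per_row == 0),
    Elbow90 = which(posture_per_row == 90)
  )
  if (length(rows) == 0) stop("condition '", condition, "' has no data")
  hals_best(E[rows, , drop = FALSE], rank, seed + seq_len(n_seeds) - 1,
            max_iter, tol)
}

#' Per-direction mean amplitudes
#'
#' Averages the trial-window mean amplitude over trials of each direction,
#' optionally after rotating Elbow-90 labels into the intrinsic frame.
#'
#' @param x Per-trial amplitudes: vector (one value per trial) or trials x
#'   time matrix (averaged over the window first).
#' @param labels Data frame with `direction` (1..n_directions) and
#'   `posture` per trial.
#' @param frame `"extrinsic"` (labels as recorded) or `"intrinsic"`.
#' @param n_directions Number of directions (default 8).
#' @param rotation_sign Passed to the intrinsic relabeling (default -1).
#' @return Named vector of `n_directions` means (names = direction index).
#' @export
direction_means <- function(x, labels, frame = c("extrinsic", "intrinsic"),
                            n_directions = 8, rotation_sign = -1) {
  frame <- match.arg(frame)
  if (is.matrix(x)) x <- rowMeans(x)
  stopifnot(length(x) == nrow(labels))
  dir <- labels$direction
  if (frame == "intrinsic") {
    rot <- labels$posture == 90
    dir[rot] <- ((dir[rot] - 1 + rotation_sign * 2) %% n_directions) + 1
  }
  m <- vapply(seq_len(n_directions), function(d) {
    if (!any(dir == d)) stop("no trials for direction ", d)
    mean(x[dir == d])
  }, numeric(1))
  names(m) <- seq_len(n_directions)
  m
}

#' Cosine tuning of per-direction mean amplitudes
#'
#' Fits `m(theta) = a0 + a1 cos(theta) + a2 sin(theta)` by ordinary least
#' squares. On equally spaced angles the design is orthogonal, so the
#' coefficients equal the discrete Fourier terms
#' `a1 = (2/K) sum m cos(theta)`, `a2 = (2/K) sum m sin(theta)`. The
#' preferred direction is `atan2(a2, a1)` in degrees mod 360 and the tuning
#' weight is `W = sqrt(a1^2 + a2^2)` (a squared variant is available).
#'
#' @param m Mean amplitude per direction.
#' @param angles_deg Direction angles (default 8 at 45 degree spacing).
#' @param normalize `"max"` (default: `m / max(m)`, making W a modulation
#'   ratio), `"mean"`, or `"none"`.
#' @param w_floor Below this W the PD is reported as `NA` (default 1e-6).
#' @param w_squared Report `W = a1^2 + a2^2` instead of the root form.
#' @return List of class `tuning_result`: `a0`, `a1`, `a2`, `pd_deg`, `w`,
#'   `r_squared`.
#' @export
cosine_tune <- function(m, angles_deg = seq(0, 315, by = 45),
                        normalize = c("max", "mean", "none"),
                        w_floor = 1e-6, w_squared = FALSE) {
  normalize <- match.arg(normalize)
  stopifnot(length(m) == length(angles_deg))
  if (length(unique(wrap_deg(angles_deg))) < 3) {
    stop("need at least 3 distinct angles")
  }
  m <- switch(normalize,
    max = if (max(m) > 0) m / max(m) else stop("cannot max-normalize all-zero m"),
    mean = if (mean(m) > 0) m / mean(m) else stop("cannot mean-normalize"),
    none = m
  )
  th <- angles_deg * pi / 180
  K <- length(m)
  spacing <- diff(sort(wrap_deg(angles_deg)))
  equal <- length(unique(round(spacing, 9))) == 1
  if (equal) {
    a0 <- mean(m)
    a1 <- 2 / K * sum(m * cos(th))
    a2 <- 2 / K * sum(m * sin(th))
  } else {
    cf <- stats::lm.fit(cbind(1, cos(th), sin(th)), m)$coefficients
    a0 <- cf[1]; a1 <- cf[2]; a2 <- cf[3]
  }
  w <- if (w_squared) a1^2 + a2^2 else sqrt(a1^2 + a2^2)
  pd <- if (sqrt(a1^2 + a2^2) > w_floor) {
    wrap_deg(atan2(a2, a1) * 180 / pi)
  } else NA_real_
  fitted <- a0 + a1 * cos(th) + a2 * sin(th)
  sst <- sum((m - mean(m))^2)
  r2 <- if (sst > 0) 1 - sum((m - fitted)^2) / sst else NA_real_
  structure(list(a0 = unname(a0), a1 = unname(a1), a2 = unname(a2),
                 pd_deg = unname(pd), w = unname(w), r_squared = unname(r2)),
            class = "tuning_result")
}

#' Preferred-direction consistency error within a module
#'
#' Elbow-90 preferred directions are first compensated by a 90 degree
#' clockwise shift; the error is the mean absolute circular deviation of
#' the compensated PDs from their circular mean.
#'
#' @param pds_deg Preferred directions in degrees (may contain `NA`).
#' @param postures Optional posture per PD (0/90); Elbow-90 entries are
#'   compensated. `NULL` skips compensation.
#' @param rotation_sign Sign of the 90 degree compensation (default -1,
#'   clockwise).
#' @return Mean absolute circular deviation in degrees, or `NA` if fewer
#'   than 2 PDs are defined.
#' @export
pd_error <- function(pds_deg, postures = NULL, rotation_sign = -1) {
  if (!is.null(postures)) {
    stopifnot(length(postures) == length(pds_deg))
    comp <- pds_deg + ifelse(postures == 90, rotation_sign * 90, 0)
  } else {
    comp <- pds_deg
  }
  if (anyNA(comp)) {
    warning("excluding ", sum(is.na(comp)), " undefined PD(s)")
    comp <- comp[!is.na(comp)]
  }
  if (length(comp) < 2) return(NA_real_)
  mu <- circ_mean_deg(comp)
  mean(abs(ang_diff_deg(comp, mu)))
}

#' Map an IC-space synergy vector to EMG channel weights
#'
#' Composites a synergy row through the magnitudes of the retained mixing
#' columns: `w_channels = |A| m`.
#'
#' @param m_row Synergy vector over ICs.
#' @param A_retained Mixing matrix restricted to the retained components
#'   (channels x ICs).
#' @return Non-negative channel weight vector.
#' @export
synergy_channel_weights <- function(m_row, A_retained) {
  stopifnot(ncol(A_retained) == length(m_row))
  as.numeric(abs(A_retained) %*% m_row)
}

#' Classify a synergy module as parallel or local
#'
#' Compares the weight-weighted spread of electrode positions along the
#' forearm axis versus around its circumference, each normalized by its
#' grid extent. Axial spread >= circumferential spread means the module is
#' structured alongside the forearm (`"parallel"`, the superficial-muscle
#' signature); otherwise it is structured in the cross-section (`"local"`,
#' the deep-muscle signature). Ties break as parallel.
#'
#' @param weights Channel weights (non-negative), one per montage channel
#'   in `channels`.
#' @param montage An `emg_montage`.
#' @param channels Montage channel indices the weights refer to (default:
#'   all non-ground channels).
#' @return `"parallel"` or `"local"`.
#' @export
classify_module_type <- function(weights, montage,
                                 channels = which(!montage$positions$is_ground)) {
  stopifnot(length(weights) == length(channels))
  if (all(weights <= 0)) stop("all-zero module weights")
  w <- weights / sum(weights)
  pos <- montage$positions[channels, ]
  ax <- pos$axial_mm / montage$forearm_length_mm
  ci <- pos$circ_deg / 360
  wsd <- function(x) {
    mu <- sum(w * x)
    sqrt(sum(w * (x - mu)^2))
  }
  if (wsd(ax) >= wsd(ci)) "parallel" else "local"
}

#' Compare tuning weights between two synergy groups
#'
#' Welch two-sample t-test with group summaries. Degenerate zero-variance
#' groups are reported with an infinite statistic (p ~ 0) unless the means
#' are equal (t = 0, p = 1).
#'
#' @param group_a,group_b Numeric vectors of tuning weights (length >= 2).
#' @return List: `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `t_statistic`, `p_value`.
#' @export
compare_tuning_weights <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  out <- list(mean_a = mean(group_a), sd_a = stats::sd(group_a),
              n_a = length(group_a),
              mean_b = mean(group_b), sd_b = stats::sd(group_b),
              n_b = length(group_b))
  tt <- tryCatch(stats::t.test(group_a, group_b, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {  # essentially constant data
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      out$t_statistic <- 0; out$p_value <- 1
    } else {
      out$t_statistic <- sign(mean(group_a) - mean(group_b)) * Inf
      out$p_value <- 0
    }
  } else {
    out$t_statistic <- unname(tt$statistic)
    out$p_value <- tt$p.value
  }
  out
}
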