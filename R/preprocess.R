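# Continuous-EMG preprocessing: zero-phase notch + band-pass filtering,
# ground-reference rejection, cursor-defined onset detection, anti-aliased
# downsampling to 50 Hz, and fixed 25-point trial epoching.

#' Filter specification for continuous EMG
#'
#' A 4th-order Butterworth band-pass (10-1000 Hz) plus a 2nd-order IIR notch
#' at 50 Hz, both applied forward-backward (zero phase). If the upper band
#' edge reaches `0.45 * fs` (reduced-rate runs), it is clamped to
#' `0.45 * fs`.
#'
#' @param notch_hz Notch frequency (default 50).
#' @param band_hz Band-pass edges in Hz (default `c(10, 1000)`).
#' @param order Butterworth order of the band-pass design (default 4).
#' @param notch_q Quality factor of the notch (default 35).
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(notch_hz = 50, band_hz = c(10, 1000), order = 4,
                        notch_q = 35) {
  stopifnot(band_hz[1] > 0, band_hz[1] < band_hz[2])
  structure(list(notch_hz = notch_hz, band_hz = band_hz, order = order,
                 notch_q = notch_q),
            class = "filter_spec")
}

# Zero-phase filtering with odd-reflection padding to suppress the edge
# transients of plain forward-backward filtering.
zp_filter <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1, 3000L)
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[pad + seq_len(n)]
}

# Biquad notch coefficients (unit DC/Nyquist gain, zeros on the unit circle).
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  r <- 1 - (w0 / q) / 2
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  # normalize DC gain to 1
  g <- sum(a) / sum(b)
  list(b = b * g, a = a)
}

#' Zero-phase notch + band-pass filtering of a recording
#'
#' @param recording List with `emg` (channels x samples) and `fs_emg`, as
#'   produced by [simulate_dataset()]; a bare matrix plus `fs` is also
#'   accepted.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate; required only when `recording` is a bare matrix.
#' @return The recording with `emg` replaced by the filtered signal.
#' @export
apply_filters <- function(recording, spec = filter_spec(), fs = NULL) {
  bare <- is.matrix(recording)
  x <- if (bare) recording else recording$emg
  fs <- if (bare) fs else recording$fs_emg
  if (is.null(fs)) stop("sampling rate unknown")
  hi <- spec$band_hz[2]
  if (hi >= 0.45 * fs) hi <- 0.45 * fs
  if (spec$band_hz[1] >= hi) stop("band edge at or above Nyquist after clamping")
  bf <- signal::butter(spec$order, c(spec$band_hz[1], hi) / (fs / 2),
                       type = "pass")
  nc <- notch_coefficients(spec$notch_hz, fs, spec$notch_q)
  notch <- signal::Arma(b = nc$b, a = nc$a)
  pad <- min(ncol(x) - 1, round(3 * fs * spec$notch_q / spec$notch_hz / 2))
  y <- t(apply(x, 1, function(ch) {
    ch <- zp_filter(bf, ch, pad = pad)
    zp_filter(notch, ch, pad = pad)
  }))
  if (bare) y else {
    recording$emg <- y
    recording
  }
}

#' Identify and remove the ground-reference channel
#'
#' The ground electrode carries no muscle signal, so it is the least
#' vibrating channel: the channel with the minimum standard deviation is
#' removed (ties broken toward the lowest index).
#'
#' @param recording Recording list (or bare matrix) with channels in rows.
#' @return List with `ground_index` and `recording` (one channel fewer;
#'   for montage-bearing recordings a `kept_channels` index vector is
#'   attached).
#' @export
select_ground_reference <- function(recording) {
  bare <- is.matrix(recording)
  x <- if (bare) recording else recording$emg
  if (nrow(x) < 2) stop("need at least 2 channels")
  sds <- apply(x, 1, stats::sd)
  gi <- which.min(sds)  # which.min takes the first minimum: lowest index
  kept <- setdiff(seq_len(nrow(x)), gi)
  if (bare) {
    return(list(ground_index = gi, recording = x[kept, , drop = FALSE],
                kept_channels = kept))
  }
  recording$emg <- x[kept, , drop = FALSE]
  recording$kept_channels <- kept
  list(ground_index = gi, recording = recording, kept_channels = kept)
}

#' Detect movement onset from a cursor trajectory
#'
#' Onset is the time of the first sample whose Euclidean displacement from
#' the trial-start position exceeds 2% of the final displacement.
#'
#' @param cursor 2 x samples matrix of cursor positions.
#' @param fs_cursor Sampling rate in Hz.
#' @param threshold Fraction of the final displacement (default 0.02).
#' @return Onset time in seconds from the start of the trajectory.
#' @export
detect_onset <- function(cursor, fs_cursor, threshold = 0.02) {
  stopifnot(is.matrix(cursor), nrow(cursor) == 2)
  disp <- sqrt(colSums((cursor - cursor[, 1])^2))
  final <- disp[length(disp)]
  if (final <= .Machine$double.eps^0.5) {
    stop("no movement: zero final cursor displacement")
  }
  k <- which(disp > threshold * final)[1]
  if (is.na(k)) stop("no sample exceeds the onset threshold")
  (k - 1) / fs_cursor
}

#' Anti-aliased downsampling
#'
#' Zero-phase 4th-order Butterworth low-pass at `0.45 * target_hz`, then
#' linear interpolation onto the target sample grid (handles non-integer
#' decimation factors such as 2048/50).
#'
#' @param x Signal matrix (signals x samples) or vector.
#' @param fs Input rate in Hz.
#' @param target_hz Output rate (default 50).
#' @return List with `x` (resampled, same orientation) and `fs`.
#' @export
downsample <- function(x, fs, target_hz = 50) {
  if (target_hz >= fs) stop("target rate must be below the input rate")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  bf <- signal::butter(4, (0.45 * target_hz) / (fs / 2), type = "low")
  t_in <- (seq_len(ncol(x)) - 1) / fs
  t_out <- seq(0, t_in[length(t_in)], by = 1 / target_hz)
  y <- t(apply(x, 1, function(ch) {
    stats::approx(t_in, zp_filter(bf, ch), xout = t_out)$y
  }))
  if (vec) y <- drop(y)
  list(x = y, fs = target_hz)
}

#' Epoch a 50 Hz signal into fixed 25-point trial windows
#'
#' Each trial spans `[onset - 0.2 s, onset + 0.3 s)`: exactly 25 samples at
#' 50 Hz. Trials whose window exceeds the signal bounds are dropped with a
#' warning.
#'
#' @param x Signals x samples matrix at `fs` Hz.
#' @param onsets_s Per-trial onset times (seconds, global).
#' @param labels Data frame with one row per onset (at least `direction`
#'   and `posture`).
#' @param fs Sampling rate of `x` (default 50).
#' @param window_s Window relative to onset (default `c(-0.2, 0.3)`).
#' @return List of class `trial_set`: `data` (trials x signals x 25 array),
#'   `labels`, `frame = "extrinsic"`, `fs`, `dropped` (indices of dropped
#'   onsets).
#' @export
epoch <- function(x, onsets_s, labels, fs = 50, window_s = c(-0.2, 0.3)) {
  stopifnot(is.matrix(x), nrow(labels) == length(onsets_s))
  n_pts <- round((window_s[2] - window_s[1]) * fs)
  keep <- logical(length(onsets_s))
  starts <- integer(length(onsets_s))
  for (i in seq_along(onsets_s)) {
    s0 <- round((onsets_s[i] + window_s[1]) * fs) + 1
    keep[i] <- s0 >= 1 && (s0 + n_pts - 1) <= ncol(x)
    starts[i] <- s0
  }
  if (any(!keep)) {
    warning(sprintf("dropped %d trial(s) with epochs outside signal bounds: %s",
                    sum(!keep), paste(which(!keep), collapse = ", ")))
  }
  idx <- which(keep)
  data <- array(0, dim = c(length(idx), nrow(x), n_pts))
  for (j in seq_along(idx)) {
    data[j, , ] <- x[, starts[idx[j]] + seq_len(n_pts) - 1, drop = FALSE]
  }
  structure(
    list(data = data, labels = labels[idx, , drop = FALSE],
         frame = "extrinsic", fs = fs, dropped = which(!keep)),
    class = "trial_set"
  )
}

#' Re-express trial direction labels in the intrinsic (forearm) frame
#'
#' Extrinsic labels are screen-fixed. In the intrinsic frame, Elbow-90
#' trials' directions are rotated 90 degrees clockwise (two 45-degree index
#' steps); Elbow-0 labels are unchanged. The operation requires an
#' extrinsic-frame trial set (applying it twice would rotate twice).
#'
#' @param trialset A `trial_set` with extrinsic labels.
#' @param frame Target frame: `"extrinsic"` or `"intrinsic"`.
#' @param rotation_sign Direction-index shift sign for the 90-degree
#'   clockwise compensation: `-1` (default) maps direction 3 to 1.
#' @return The trial set with rotated labels and updated `frame` tag.
#' @export
relabel_frame <- function(trialset, frame = c("extrinsic", "intrinsic"),
                          rotation_sign = -1) {
  frame <- match.arg(frame)
  stopifnot(inherits(trialset, "trial_set"))
  if (frame == "extrinsic") return(trialset)
  if (!identical(trialset$frame, "extrinsic")) {
    stop("relabel_frame must start from an extrinsic-frame trial set")
  }
  lb <- trialset$labels
  rot <- lb$posture == 90
  lb$direction[rot] <- ((lb$direction[rot] - 1 + rotation_sign * 2) %% 8) + 1
  if ("direction_deg" %in% names(lb)) {
    lb$direction_deg[rot] <- wrap_deg(lb$direction_deg[rot] + rotation_sign * 90)
  }
  trialset$labels <- lb
  trialset$frame <- "intrinsic"
  trialset
}
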