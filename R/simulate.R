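# Synthetic multi-channel forearm EMG with known ground truth: cylindrical
# electrode grid, direction-tuned superficial/deep sources, envelope-
# modulated band-limited carriers, line + sensor noise, cursor trajectories.

#' Simulation configuration
#'
#' Defaults are the desk-scale study conditions: 8 cursor directions at 45
#' degree spacing, two elbow postures (0 and 90 degrees), `n_reps`
#' repetitions per direction x posture cell, 2 s trials. Full-scale
#' recordings (2048 Hz, 80 repetitions) are obtained by overriding `fs_emg`
#' and `n_reps`.
#'
#' @param fs_emg EMG sampling rate in Hz (default 1024; full scale 2048).
#' @param fs_cursor Cursor sampling rate in Hz (default 100).
#' @param trial_duration_s Trial length in seconds (default 2).
#' @param gap_s Inter-trial gap in seconds (default 0.5).
#' @param n_reps Repetitions per direction x posture cell (default 10; full
#'   scale 80).
#' @param directions_deg Target directions in degrees (default 8 at 45
#'   degree spacing; direction index k maps to `(k-1)*45` degrees).
#' @param postures_deg Elbow angles in degrees (default `c(0, 90)`).
#' @param snr_db Power ratio (dB) of the mixed muscle-source signal to white
#'   sensor noise; `Inf` disables sensor noise.
#' @param line_amp Amplitude of 50 Hz line interference relative to the RMS
#'   of the clean mixed signal; 0 disables it.
#' @param baseline_amp Amplitude of per-channel baseline noise (broadband
#'   carrier with a slowly varying random amplitude, independent across
#'   channels: electrode/skin-contact noise) relative to the clean-signal
#'   RMS; 0 disables it.
#' @param baseline_env_hz Bandwidth of the baseline-noise amplitude
#'   fluctuations (default 0.5 Hz).
#' @param ground_noise_scale Noise amplitude on the ground electrode
#'   relative to the other channels (default 0.5): the actively driven
#'   ground on the hand dorsum sees no muscle signal and suppressed
#'   common-mode noise, making it the least vibrating channel.
#' @param line_hz Line frequency (default 50).
#' @param onset_latency_s Delay from trial start to movement onset.
#' @param ramp_s Envelope rise time after onset.
#' @param cursor_ramp_s Cursor travel time from origin to target.
#' @param carrier_band_hz Band of the EMG carrier noise; the upper edge is
#'   clamped to `0.45 * fs_emg`.
#' @param seed Integer seed; a fixed seed makes the dataset byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs_emg = 1024, fs_cursor = 100,
                       trial_duration_s = 2, gap_s = 0.5, n_reps = 10,
                       directions_deg = seq(0, 315, by = 45),
                       postures_deg = c(0, 90),
                       snr_db = 10, line_amp = 0.05, line_hz = 50,
                       baseline_amp = 0.2, baseline_env_hz = 0.5,
                       ground_noise_scale = 0.5,
                       onset_latency_s = 0.4, ramp_s = 0.15,
                       cursor_ramp_s = 1,
                       carrier_band_hz = c(20, 450), seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.infinite(snr_db) && snr_db < 0) stop("snr_db = -Inf is not allowed")
  band <- carrier_band_hz
  band[2] <- min(band[2], 0.45 * fs_emg)
  if (band[1] >= band[2]) stop("carrier band collapses at this fs_emg")
  structure(
    list(fs_emg = fs_emg, fs_cursor = fs_cursor,
         trial_duration_s = trial_duration_s, gap_s = gap_s,
         n_reps = n_reps, directions_deg = directions_deg,
         postures_deg = postures_deg, snr_db = snr_db,
         line_amp = line_amp, line_hz = line_hz,
         baseline_amp = baseline_amp, baseline_env_hz = baseline_env_hz,
         ground_noise_scale = ground_noise_scale,
         onset_latency_s = onset_latency_s, ramp_s = ramp_s,
         cursor_ramp_s = cursor_ramp_s, carrier_band_hz = band,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default planted source set
#'
#' Four superficial sources with local footprints and two deep sources with
#' cross-sectional footprints, all cosine-tuned in the intrinsic (forearm)
#' frame with preferred directions spread over the circle, plus one untuned
#' broadband baseline-noise source. Positions span the grid.
#'
#' @param montage An `emg_montage` (used for sensible default positions).
#' @return List of `source_spec` objects.
#' @export
default_sources <- function(montage = build_montage()) {
  len <- montage$forearm_length_mm
  list(
    source_spec("superficial", axial_mm = 0.20 * len, circ_deg = 0,
                a0 = 0.5, w = 0.40, pd_deg = 0),
    source_spec("superficial", axial_mm = 0.45 * len, circ_deg = 90,
                a0 = 0.5, w = 0.40, pd_deg = 90),
    source_spec("superficial", axial_mm = 0.70 * len, circ_deg = 180,
                a0 = 0.5, w = 0.40, pd_deg = 180),
    source_spec("superficial", axial_mm = 0.30 * len, circ_deg = 270,
                a0 = 0.5, w = 0.40, pd_deg = 270),
    source_spec("deep", axial_mm = 0.35 * len, circ_deg = 45, depth_mm = 20,
                a0 = 0.5, w = 0.35, pd_deg = 45),
    source_spec("deep", axial_mm = 0.60 * len, circ_deg = 225, depth_mm = 20,
                a0 = 0.5, w = 0.35, pd_deg = 225),
    source_spec("noise", axial_mm = 0.50 * len, circ_deg = 135, depth_mm = 10,
                a0 = 0.35, w = 0, pd_deg = 0, frame = "extrinsic")
  )
}

# Cosine-tuned activation level of one source for a screen direction under a
# posture. Intrinsic-frame sources see the screen direction rotated by the
# elbow angle (clockwise), extrinsic sources do not.
source_level <- function(src, direction_deg, posture_deg) {
  if (src$kind == "noise") return(src$a0)
  theta_eff <- if (src$frame == "intrinsic") {
    direction_deg - posture_deg
  } else {
    direction_deg
  }
  max(0, src$a0 + src$w * cos((theta_eff - src$pd_deg) * pi / 180))
}

# Band-limited unit-mean-rectified carrier noise of length n.
make_carrier <- function(n, fs, band) {
  x <- stats::rnorm(n + 2 * fs)  # pad to absorb filter edge transients
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  x <- x[(fs + 1):(fs + n)]
  x / mean(abs(x))
}

#' Simulate a single trial
#'
#' Each source's envelope is its cosine-tuned level ramped on after the
#' onset latency; the source signal is that envelope modulating an
#' independent band-limited carrier whose mean rectified amplitude is one,
#' so the mean rectified source amplitude reproduces the tuned level. The
#' EMG is the lead-field mixture plus 50 Hz line interference and white
#' sensor noise at `snr_db`. The cursor ramps linearly from the origin to
#' the unit target after the onset latency.
#'
#' @param direction_deg Screen target direction in degrees.
#' @param posture_deg Elbow angle (0 or 90).
#' @param sources List of `source_spec`.
#' @param A_true Lead-field matrix (channels x sources).
#' @param config A `sim_config`.
#' @param seed Seed for this trial's draws (default `config$seed`).
#' @param noise_sd Sensor-noise SD; if `NULL`, derived from this trial's
#'   clean signal power and `config$snr_db`.
#' @return List with `emg` (channels x samples), `cursor` (2 x cursor
#'   samples), `envelopes` (sources x samples), `source_signals`,
#'   `onset_true_s`.
#' @export
simulate_trial <- function(direction_deg, posture_deg, sources, A_true,
                           config, seed = config$seed, noise_sd = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!isTRUE(any(abs(ang_diff_deg(direction_deg, config$directions_deg)) < 1e-9))) {
    stop("direction_deg not in the configured direction set")
  }
  fs <- config$fs_emg
  n <- round(config$trial_duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  ramp <- ramp_profile(t, config$onset_latency_s, config$ramp_s)
  with_seed(seed, {
    env <- t(vapply(sources, function(src) {
      lev <- source_level(src, direction_deg, posture_deg)
      if (src$kind == "noise") rep(lev, n) else lev * ramp
    }, numeric(n)))
    S <- env * t(vapply(seq_along(sources), function(i) {
      make_carrier(n, fs, config$carrier_band_hz)
    }, numeric(n)))
    clean <- A_true %*% S
    emg <- clean
    if (config$line_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      gains <- stats::runif(nrow(A_true), 0.5, 1.5)
      line <- config$line_amp * sqrt(mean(clean^2)) *
        outer(gains, sin(2 * pi * config$line_hz * t + phase))
      emg <- emg + line
    }
    if (is.finite(config$snr_db)) {
      if (is.null(noise_sd)) {
        noise_sd <- sqrt(mean(clean^2) / 10^(config$snr_db / 10))
      }
      emg <- emg + noise_sd * matrix(stats::rnorm(length(emg)), nrow(emg))
    }
    nc <- round(config$trial_duration_s * config$fs_cursor)
    tc <- (seq_len(nc) - 1) / config$fs_cursor
    prog <- pmin(pmax((tc - config$onset_latency_s) / config$cursor_ramp_s, 0), 1)
    target <- c(cos(direction_deg * pi / 180), sin(direction_deg * pi / 180))
    cursor <- rbind(target[1] * prog, target[2] * prog)
    list(emg = emg, cursor = cursor, envelopes = env, source_signals = S,
         onset_true_s = config$onset_latency_s)
  })
}

# Half-cosine rise from 0 to 1 starting at `latency` over `ramp_s` seconds.
ramp_profile <- function(t, latency, ramp_s) {
  u <- pmin(pmax((t - latency) / ramp_s, 0), 1)
  (1 - cos(pi * u)) / 2
}

#' Simulate a full multi-trial recording with ground truth
#'
#' Produces `8 directions x 2 postures x n_reps` trials in seeded random
#' order, concatenated into one continuous recording with inter-trial gaps
#' (sensor/line noise only). Sensor-noise SD is calibrated once from the
#' mean clean-signal power over all trials so the realized dataset-level
#' power ratio equals `snr_db`.
#'
#' @param config A `sim_config`.
#' @param sources List of `source_spec` (default [default_sources()]).
#' @param montage An `emg_montage` (default [build_montage()]).
#' @return A list of class `sim_dataset` with elements `recording` (list:
#'   `emg`, `fs_emg`, `montage`, `cursor`, `fs_cursor`) and `truth` (list:
#'   `A_true`, `envelopes`, `source_signals`, `sources`, `labels`,
#'   `noise_sd`). `labels` is a data.frame with one row per trial:
#'   `trial`, `direction` (1-8), `direction_deg`, `posture`, `t_start_s`,
#'   `onset_true_s` (global time).
#' @export
simulate_dataset <- function(config = sim_config(),
                             sources = NULL,
                             montage = build_montage()) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sources)) sources <- default_sources(montage)
  A_true <- make_leadfield(montage, sources)
  n_dir <- length(config$directions_deg)
  n_pos <- length(config$postures_deg)
  cells <- expand.grid(direction = seq_len(n_dir),
                       posture_i = seq_len(n_pos))
  design <- cells[rep(seq_len(nrow(cells)), each = config$n_reps), ]
  order_idx <- with_seed(config$seed, sample(nrow(design)))
  design <- design[order_idx, , drop = FALSE]
  n_trials <- nrow(design)

  fs <- config$fs_emg
  n_tr <- round(config$trial_duration_s * fs)
  n_gap <- round(config$gap_s * fs)
  n_tot <- n_trials * (n_tr + n_gap)
  nc_tr <- round(config$trial_duration_s * config$fs_cursor)
  nc_gap <- round(config$gap_s * config$fs_cursor)
  nc_tot <- n_trials * (nc_tr + nc_gap)
  n_ch <- nrow(A_true)
  n_src <- length(sources)

  # first pass: simulate clean trials to calibrate one dataset-level noise SD
  trials <- vector("list", n_trials)
  clean_power <- numeric(n_trials)
  cfg_clean <- config
  cfg_clean$snr_db <- Inf
  cfg_clean$line_amp <- 0  # line interference is added continuously below
  for (i in seq_len(n_trials)) {
    d <- design$direction[i]
    p <- config$postures_deg[design$posture_i[i]]
    trials[[i]] <- simulate_trial(config$directions_deg[d], p, sources,
                                  A_true, cfg_clean,
                                  seed = derive_seed(config$seed, paste0("trial", i)))
    clean_power[i] <- mean(trials[[i]]$emg^2)
  }
  noise_sd <- if (is.finite(config$snr_db)) {
    sqrt(mean(clean_power) / 10^(config$snr_db / 10))
  } else 0

  emg <- matrix(0, n_ch, n_tot)
  cursor <- matrix(0, 2, nc_tot)
  envelopes <- matrix(0, n_src, n_tot)
  source_signals <- matrix(0, n_src, n_tot)
  labels <- data.frame(trial = seq_len(n_trials),
                       direction = design$direction,
                       direction_deg = config$directions_deg[design$direction],
                       posture = config$postures_deg[design$posture_i],
                       t_start_s = NA_real_, onset_true_s = NA_real_)
  for (i in seq_len(n_trials)) {
    i0 <- (i - 1) * (n_tr + n_gap)
    idx <- i0 + seq_len(n_tr)
    emg[, idx] <- trials[[i]]$emg
    envelopes[, idx] <- trials[[i]]$envelopes
    source_signals[, idx] <- trials[[i]]$source_signals
    ic0 <- (i - 1) * (nc_tr + nc_gap)
    cursor[, ic0 + seq_len(nc_tr)] <- trials[[i]]$cursor
    labels$t_start_s[i] <- i0 / fs
    labels$onset_true_s[i] <- i0 / fs + trials[[i]]$onset_true_s
  }
  gscale <- rep(1, n_ch)
  gscale[montage$ground_index] <- config$ground_noise_scale %||% 0.5
  with_seed(derive_seed(config$seed, "sensor_noise"), {
    if (noise_sd > 0) {
      emg <- emg + (gscale * noise_sd) * matrix(stats::rnorm(length(emg)), n_ch)
    }
    if (config$line_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      gains <- stats::runif(n_ch, 0.5, 1.5) * gscale
      amp <- config$line_amp * sqrt(mean(clean_power))
      tt <- (seq_len(n_tot) - 1) / fs
      emg <- emg + amp * outer(gains, sin(2 * pi * config$line_hz * tt + phase))
    }
    if (config$baseline_amp > 0) {
      # per-channel electrode/skin baseline noise: broadband carrier with a
      # slowly varying random amplitude, independent across channels
      amp <- config$baseline_amp * sqrt(mean(clean_power))
      env_lp <- signal::butter(2, min(config$baseline_env_hz / (fs / 2), 0.9),
                               type = "low")
      for (ch in seq_len(n_ch)) {
        slow <- signal::filtfilt(env_lp, stats::rnorm(n_tot))
        slow <- pmax(0, 1 + slow / max(stats::sd(slow), 1e-12))
        emg[ch, ] <- emg[ch, ] +
          (amp * gscale[ch]) * slow * make_carrier(n_tot, fs, config$carrier_band_hz)
      }
    }
  })
  structure(
    list(
      recording = list(emg = emg, fs_emg = fs, montage = montage,
                       cursor = cursor, fs_cursor = config$fs_cursor),
      truth = list(A_true = A_true, envelopes = envelopes,
                   source_signals = source_signals, sources = sources,
                   labels = labels, noise_sd = noise_sd),
      config = config
    ),
    class = "sim_dataset"
  )
}
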