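# Synthetic-data generator: montage geometry, lead-field structure, trial
# signal model, and dataset-level ground-truth consistency.

test_that("montage lays a regular cylindrical grid with a hand-dorsum ground", {
  m <- build_montage()
  expect_equal(m$n_channels, 96)
  expect_equal(m$ground_index, 96)
  surf <- m$positions[!m$positions$is_ground, ]
  expect_false(any(duplicated(surf[, c("axial_mm", "circ_deg")])))
  # constant axial spacing between adjacent rings
  ax <- sort(unique(surf$axial_mm))
  expect_true(all(abs(diff(diff(ax))) < 1e-9))
  # ground sits distal to the forearm grid
  expect_gt(m$positions$axial_mm[m$ground_index], max(surf$axial_mm))
  expect_error(build_montage(0, 8), "positive")
  expect_error(build_montage(1, 1), "at least 2")
})

test_that("lead field is local for superficial and ring-spread for deep sources", {
  m <- build_montage()
  sup <- source_spec("superficial", axial_mm = 90, circ_deg = 45)
  deep <- source_spec("deep", axial_mm = 90, circ_deg = 45, depth_mm = 20)
  A <- make_leadfield(m, list(sup, deep))
  expect_true(all(A >= 0 & A <= 1))
  # superficial column peaks at the channel directly under the source
  under <- which(m$positions$axial_mm == 90 & m$positions$circ_deg == 45)
  expect_equal(which.max(A[, 1]), under)
  # over the ring at the source's axial position, deep weights vary less
  ring <- which(m$positions$axial_mm == 90 & !m$positions$is_ground)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(A[ring, 2]), cv(A[ring, 1]))
  expect_error(make_leadfield(m, list()), "empty")
})

test_that("trial simulation is seed-reproducible and cosine-tuned", {
  cfg <- sim_config(fs_emg = 512, trial_duration_s = 1, seed = 7,
                    snr_db = Inf, line_amp = 0, baseline_amp = 0)
  m <- build_montage(4, 4)
  src <- list(source_spec("superficial", axial_mm = 60, circ_deg = 0,
                          a0 = 0.5, w = 0.4, pd_deg = 90))
  A <- make_leadfield(m, src)
  t1 <- simulate_trial(90, 0, src, A, cfg, seed = 3)
  t2 <- simulate_trial(90, 0, src, A, cfg, seed = 3)
  expect_identical(t1$emg, t2$emg)
  expect_identical(t1$cursor, t2$cursor)
  # mean rectified source amplitude is maximal when moving along the PD, and
  # reproduces the tuned level within 2% on the post-ramp plateau
  plateau <- seq_len(512)[(seq_len(512) - 1) / 512 > 0.55]
  amp <- vapply(cfg$directions_deg, function(d) {
    tr <- simulate_trial(d, 0, src, A, cfg, seed = 11)
    mean(abs(tr$source_signals[1, plateau]))
  }, numeric(1))
  expect_equal(which.max(amp), which(cfg$directions_deg == 90))
  level <- pmax(0, 0.5 + 0.4 * cos((cfg$directions_deg - 90) * pi / 180))
  expect_true(all(abs(amp - level) / max(level) < 0.02))
  expect_error(simulate_trial(13, 0, src, A, cfg), "direction")
})

test_that("intrinsic-frame sources see the screen direction rotated by the elbow angle", {
  cfg <- sim_config(fs_emg = 512, trial_duration_s = 1, seed = 7,
                    snr_db = Inf, line_amp = 0, baseline_amp = 0)
  m <- build_montage(4, 4)
  src <- list(source_spec("superficial", axial_mm = 60, circ_deg = 0,
                          a0 = 0.5, w = 0.4, pd_deg = 0, frame = "intrinsic"))
  A <- make_leadfield(m, src)
  # at posture 90, the response to screen direction (PD + 90) matches the
  # posture-0 response to the PD itself
  e0 <- simulate_trial(0, 0, src, A, cfg, seed = 5)$envelopes
  e90 <- simulate_trial(90, 90, src, A, cfg, seed = 5)$envelopes
  expect_equal(e0, e90)
})

test_that("dataset has a balanced seeded design with calibrated SNR", {
  ds <- tiny_sim()
  lb <- ds$truth$labels
  expect_equal(nrow(lb), 8 * 2 * 2)
  expect_true(all(table(lb$direction, lb$posture) == ds$config$n_reps))
  # SNR calibration: reconstruct the clean mixture from the truth block
  cfg <- sim_config(fs_emg = 512, trial_duration_s = 1, gap_s = 0.3,
                    n_reps = 2, onset_latency_s = 0.4, ramp_s = 0.1,
                    cursor_ramp_s = 0.5, seed = 9, snr_db = 10,
                    line_amp = 0, baseline_amp = 0)
  ds2 <- simulate_dataset(cfg)
  clean <- ds2$truth$A_true %*% ds2$truth$source_signals
  noise <- ds2$recording$emg - clean
  active <- colSums(abs(ds2$truth$source_signals)) > 0
  realized_db <- 10 * log10(mean(clean[, active]^2) / mean(noise^2))
  expect_lt(abs(realized_db - 10), 0.5)
})

test_that("identical config yields byte-identical datasets", {
  cfg <- sim_config(fs_emg = 512, trial_duration_s = 1, gap_s = 0.3,
                    n_reps = 1, seed = 31)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})

test_that("with noise off the mixing matrix is recoverable by least squares", {
  ds <- tiny_sim(noise = FALSE)
  S <- ds$truth$source_signals
  X <- ds$recording$emg
  A_hat <- X %*% t(S) %*% solve(S %*% t(S))
  expect_lt(max(abs(A_hat - ds$truth$A_true)), 1e-8)
})

test_that("planted tuning is recovered from true envelopes (generator-estimator closed loop)", {
  ds <- tiny_sim(noise = FALSE)
  cfg <- ds$config
  lb <- ds$truth$labels
  fs <- cfg$fs_emg
  n_tr <- round(cfg$trial_duration_s * fs)
  n_gap <- round(cfg$gap_s * fs)
  plateau0 <- which((seq_len(n_tr) - 1) / fs > cfg$onset_latency_s + cfg$ramp_s)
  for (k in seq_along(ds$truth$sources)) {
    src <- ds$truth$sources[[k]]
    if (src$kind == "noise") next
    tm <- vapply(seq_len(nrow(lb)), function(i) {
      i0 <- (i - 1) * (n_tr + n_gap)
      mean(ds$truth$envelopes[k, i0 + plateau0])
    }, numeric(1))
    m <- direction_means(tm, lb, frame = "intrinsic")
    tr <- cosine_tune(m, normalize = "none")
    dpd <- abs(((tr$pd_deg - src$pd_deg + 180) %% 360) - 180)
    expect_lt(dpd, 1)
    expect_lt(abs(tr$w - src$w) / src$w, 0.02)
    expect_lt(abs(tr$a0 - src$a0) / src$a0, 0.02)
  }
})
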