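# Preprocessing: zero-phase filtering, ground rejection, onset detection,
# downsampling and 25-point epoching.

test_that("band-pass + notch filtering removes DC and 50 Hz but passes 100 Hz", {
  fs <- 1024
  t <- seq(0, 10, by = 1 / fs)
  sine <- function(f) matrix(sin(2 * pi * f * t), 1)
  y_dc <- apply_filters(matrix(2.5, 1, length(t)), filter_spec(), fs = fs)
  expect_lt(max(abs(y_dc)), 1e-6)
  y50 <- apply_filters(sine(50), filter_spec(), fs = fs)
  expect_lt(stats::sd(y50) / stats::sd(sine(50)), 0.05)
  y100 <- apply_filters(sine(100), filter_spec(), fs = fs)
  expect_gt(stats::sd(y100) / stats::sd(sine(100)), 0.90)
})

test_that("filtering is linear in its input", {
  fs <- 512
  x <- matrix(stats::rnorm(3 * 4096), 3)
  y1 <- apply_filters(3.7 * x, filter_spec(), fs = fs)
  y2 <- 3.7 * apply_filters(x, filter_spec(), fs = fs)
  expect_equal(y1, y2, tolerance = 1e-10)
})

test_that("band edges at or above Nyquist after clamping are rejected", {
  x <- matrix(stats::rnorm(2 * 1000), 2)
  expect_error(apply_filters(x, filter_spec(band_hz = c(10, 1000)), fs = 22),
               "Nyquist")
})

test_that("ground-reference rejection removes the least vibrating channel", {
  set.seed(4)
  x <- matrix(stats::rnorm(96 * 2000), 96)
  x[41, ] <- 0.001 * stats::rnorm(2000)  # near-constant ground
  gr <- select_ground_reference(x)
  expect_equal(gr$ground_index, 41)
  expect_equal(nrow(gr$recording), 95)
  # tie in SD -> lowest index removed
  xt <- rbind(rep(c(-1, 1), 50), rep(c(-1, 1), 50), stats::rnorm(100) * 10)
  expect_equal(select_ground_reference(xt)$ground_index, 1)
  x2 <- rbind(stats::rnorm(500), 0.1 * stats::rnorm(500))
  expect_equal(select_ground_reference(x2)$ground_index, 2)
  expect_error(select_ground_reference(matrix(1:5, 1)), "2 channels")
})

test_that("onset detection matches the 2% ramp arithmetic", {
  fs <- 100
  # linear ramp 0 -> 1 over 100 samples: first sample strictly above 0.02
  ramp <- seq(0, 1, length.out = 100)
  cur <- rbind(ramp, 0)
  k_expected <- which(ramp > 0.02 * ramp[100])[1]
  expect_equal(detect_onset(cur, fs), (k_expected - 1) / fs)
  # step function at sample k
  step <- c(rep(0, 30), rep(1, 70))
  expect_equal(detect_onset(rbind(step, 0), fs), 30 / fs)
  expect_error(detect_onset(matrix(0, 2, 50), fs), "zero final")
})

test_that("downsampling preserves duration, DC and slow components", {
  fs <- 2048
  t <- seq(0, 5, by = 1 / fs)
  d <- downsample(matrix(1, 1, length(t)), fs, 50)
  expect_equal(d$fs, 50)
  expect_lt(abs(ncol(d$x) / 50 - 5), 1 / 50 + 1e-9)
  expect_lt(max(abs(d$x - 1)), 1e-6)
  s <- downsample(sin(2 * pi * 1 * t), fs, 50)
  mid <- s$x[25:225]
  expect_lt(abs(max(mid) - 1), 0.01)
  expect_error(downsample(matrix(1, 1, 100), 50, 50), "below")
})

test_that("epochs are exactly 25 samples spanning [-0.2, 0.3) around onset", {
  x <- matrix(seq_len(200), 1)  # 4 s at 50 Hz, values = sample index
  lb <- data.frame(direction = c(1, 2, 3), posture = c(0, 0, 90))
  expect_warning(
    ts <- epoch(x, c(1.0, 0.1, 2.0), lb),
    "dropped 1 trial"
  )
  expect_equal(dim(ts$data), c(2, 1, 25))
  # onset 1.0 s -> samples 41..65 (0.80 .. 1.28 s)
  expect_equal(ts$data[1, 1, ], as.numeric(41:65))
  expect_equal(ts$dropped, 2L)
  expect_equal(ts$labels$direction, c(1, 3))
  # conservation: n valid onsets -> n trials
  ts2 <- epoch(x, c(0.5, 1.5, 2.5, 3.2), data.frame(direction = 1:4,
                                                    posture = 0))
  expect_equal(dim(ts2$data)[1], 4)
})

test_that("intrinsic relabeling rotates Elbow-90 directions two index steps clockwise", {
  x <- matrix(stats::rnorm(2 * 300), 2)
  lb <- data.frame(direction = c(3, 3, 1, 8), posture = c(0, 90, 90, 90))
  ts <- epoch(x, c(1, 2, 3, 4), lb)
  intr <- relabel_frame(ts, "intrinsic")
  expect_equal(intr$labels$direction, c(3, 1, 7, 6))
  expect_equal(intr$frame, "intrinsic")
  # Elbow-0 trials identical in both frames
  expect_equal(relabel_frame(ts, "extrinsic")$labels$direction[1], 3)
  # must start from extrinsic labels
  expect_error(relabel_frame(intr, "intrinsic"), "extrinsic")
})

test_that("intrinsic relabeling makes planted per-direction envelopes posture-invariant", {
  ds <- tiny_sim(noise = FALSE)
  cfg <- ds$config
  lb <- ds$truth$labels
  fs <- cfg$fs_emg
  n_tr <- round(cfg$trial_duration_s * fs)
  n_gap <- round(cfg$gap_s * fs)
  plateau0 <- which((seq_len(n_tr) - 1) / fs > cfg$onset_latency_s + cfg$ramp_s)
  k <- 1  # an intrinsic-frame tuned source
  tm <- vapply(seq_len(nrow(lb)), function(i) {
    mean(ds$truth$envelopes[k, (i - 1) * (n_tr + n_gap) + plateau0])
  }, numeric(1))
  by_post <- function(frame) {
    vapply(c(0, 90), function(p) {
      direction_means(tm[lb$posture == p], lb[lb$posture == p, ],
                      frame = frame)
    }, numeric(8))
  }
  intr <- by_post("intrinsic")
  extr <- by_post("extrinsic")
  expect_lt(max(abs(intr[, 1] - intr[, 2])), 1e-9)
  expect_gt(max(abs(extr[, 1] - extr[, 2])), 0.1)
})
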