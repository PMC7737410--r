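# Synergy-module analysis: scalar product, UPGMA clustering, cosine tuning,
# PD consistency, module typing, and group comparisons.

test_that("scalar product matches normalized inner-product arithmetic", {
  expect_equal(scalar_product(c(2, 1, 3), c(2, 1, 3)), 1)
  expect_equal(scalar_product(c(1, 0), c(0, 1)), 0)
  expect_equal(scalar_product(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(scalar_product(c(0, 0), c(1, 1)), "zero")
  expect_error(scalar_product(c(-1, 1), c(1, 1)), "non-negative")
  # symmetry and scale invariance over random non-negative pairs
  set.seed(1)
  for (i in 1:20) {
    a <- stats::runif(6); b <- stats::runif(6)
    expect_equal(scalar_product(a, b), scalar_product(b, a))
    expect_equal(scalar_product(3.3 * a, b), scalar_product(a, b))
  }
})

test_that("UPGMA clustering matches threshold intuition and stated examples", {
  all9 <- matrix(0.9, 3, 3); diag(all9) <- 1
  expect_equal(length(unique(upgma_cluster(all9))), 1)
  ident <- diag(4)
  expect_equal(length(unique(upgma_cluster(ident))), 4)
  sp <- diag(4)
  sp[1, 2] <- sp[2, 1] <- 0.9
  sp[3, 4] <- sp[4, 3] <- 0.8
  sp[sp == 0] <- 0.3; diag(sp) <- 1
  as <- upgma_cluster(sp)
  expect_true(as[1] == as[2] && as[3] == as[4] && as[1] != as[3])
  expect_error(upgma_cluster(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("UPGMA equals the exhaustive average-linkage oracle on random draws", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    v <- stats::runif(n * (n - 1) / 2)
    sp <- diag(n)
    sp[lower.tri(sp)] <- v
    sp <- sp + t(sp); diag(sp) <- 1
    expect_true(same_partition(upgma_cluster(sp), brute_upgma(sp)))
  }
})

test_that("cosine tuning recovers planted parameters exactly on 8 angles", {
  th <- seq(0, 315, by = 45)
  m <- 0.5 + 0.3 * cos((th - 60) * pi / 180)
  tr <- cosine_tune(m, normalize = "none")
  expect_equal(tr$a0, 0.5, tolerance = 1e-12)
  expect_equal(tr$w, 0.3, tolerance = 1e-12)
  expect_equal(tr$pd_deg, 60, tolerance = 1e-10)
  # closed form equals the generic least-squares oracle
  cf <- stats::lm(m ~ cos(th * pi / 180) + sin(th * pi / 180))$coefficients
  expect_equal(unname(cf), c(tr$a0, tr$a1, tr$a2), tolerance = 1e-10)
  # atan2 branch: PD near 360 stays in [0, 360)
  m2 <- 0.5 + 0.3 * cos((th - 350) * pi / 180)
  expect_equal(cosine_tune(m2, normalize = "none")$pd_deg, 350,
               tolerance = 1e-10)
  # constant tuning: W = 0, PD undefined
  trc <- cosine_tune(rep(2, 8), normalize = "none")
  expect_equal(trc$w, 0, tolerance = 1e-12)
  expect_true(is.na(trc$pd_deg))
  expect_error(cosine_tune(c(1, 2), c(0, 180)), "3 distinct")
})

test_that("per-direction means are label-driven and order-invariant", {
  lb <- data.frame(direction = rep(1:8, each = 3), posture = 0)
  x <- rep(5, 24)
  expect_true(all(direction_means(x, lb) == 5))
  set.seed(2)
  x2 <- stats::runif(24)
  p <- sample(24)
  expect_equal(direction_means(x2, lb), direction_means(x2[p], lb[p, ]))
  expect_error(direction_means(x2[1:21], lb[1:21, ]), "direction 8")
})

test_that("PD error is a wraparound-aware mean circular deviation", {
  expect_equal(pd_error(c(10, 30)), 10)
  expect_equal(pd_error(c(359, 1)), 1)
  expect_equal(pd_error(c(123, 123, 123)), 0)
  # Elbow-90 compensation: PDs identical after the 90 deg clockwise shift
  expect_equal(pd_error(c(40, 130), postures = c(0, 90)), 0)
  expect_warning(e <- pd_error(c(10, NA, 30), postures = c(0, 0, 0)),
                 "undefined")
  expect_equal(e, 10)
  expect_true(is.na(suppressWarnings(pd_error(c(10, NA)))))
})

test_that("module typing separates axial from cross-sectional weight patterns", {
  m <- build_montage()
  pos <- m$positions
  ch <- which(!pos$is_ground)
  w_col <- as.numeric(pos$circ_deg[ch] == 0)          # one axial column
  expect_equal(classify_module_type(w_col, m, ch), "parallel")
  w_ring <- as.numeric(pos$axial_mm[ch] == pos$axial_mm[1])  # one ring
  expect_equal(classify_module_type(w_ring, m, ch), "local")
  expect_equal(classify_module_type(rep(1, length(ch)), m, ch), "parallel")
  expect_error(classify_module_type(rep(0, length(ch)), m, ch), "zero")
})

test_that("tuning-weight comparison reports Welch statistics with degenerate guards", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  same <- compare_tuning_weights(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(3)
  lo <- abs(stats::rnorm(6, 0, 1e-3))
  hi <- 1 + abs(stats::rnorm(6, 0, 1e-3))
  cmp <- compare_tuning_weights(lo, hi)
  expect_lt(cmp$p_value, 0.01)
  swap <- compare_tuning_weights(hi, lo)
  expect_equal(swap$t_statistic, -cmp$t_statistic)
  expect_equal(swap$p_value, cmp$p_value)
  const <- compare_tuning_weights(c(0, 0, 0), c(1, 1, 1))
  expect_true(is.infinite(const$t_statistic))
  expect_equal(const$p_value, 0)
})

test_that("condition factorization subsets rows and reproduces the Total fit", {
  pl <- planted_envelopes(K = 3, seed = 8)
  posture <- rep(c(0, 90), length.out = nrow(pl$E))
  tot <- condition_synergies(pl$E, posture, "Total", rank = 3, seed = 4,
                             n_seeds = 2)
  direct <- emgsynergy:::hals_best(pl$E, 3, 4 + 0:1, 300, 1e-7)
  expect_identical(tot$T, direct$T)
  e0 <- condition_synergies(pl$E, posture, "Elbow0", rank = 3, seed = 4,
                            n_seeds = 2)
  expect_equal(nrow(e0$T), sum(posture == 0))
  expect_error(condition_synergies(pl$E, rep(NA_real_, nrow(pl$E)), "Elbow0",
                                   rank = 3), "no data")
})
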