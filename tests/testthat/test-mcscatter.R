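# Monte Carlo engine: coarse folding, estimator linearity, the kinematic
# Compton floor, seed determinism and smoothness of the down-scatter term.

test_that("coarse folding conserves activity and averages attenuation", {
  set.seed(4)
  v <- array(runif(32^3), c(32, 32, 32))
  expect_identical(coarse_fold(v, 1), v)
  f2 <- coarse_fold(v, 2, "sum")
  expect_equal(dim(f2), c(16, 16, 16))
  expect_identical(sum(f2), sum(v))
  m2 <- coarse_fold(v, 2, "mean")
  blk <- v[1:2, 1:2, 1:2]
  expect_equal(m2[1, 1, 1], mean(blk))
  expect_true(m2[1, 1, 1] >= min(blk) && m2[1, 1, 1] <= max(blk))
  expect_error(coarse_fold(array(0, c(30, 30, 30)), 4), "divide")
})

test_that("scatter estimates are deterministic, finite and non-negative", {
  ph <- small_phantom(3)
  geom <- small_geometry()
  coll <- collimator_model()
  mc <- mc_config(photons = 2e4, seed = 77L)
  e1 <- simulate_scatter(ph$tc, ph$mu_map, 140, energy_window(140), geom, coll, mc)
  e2 <- simulate_scatter(ph$tc, ph$mu_map, 140, energy_window(140), geom, coll, mc)
  expect_identical(e1$scatter$counts, e2$scatter$counts)
  expect_true(all(is.finite(e1$scatter$counts)))
  expect_true(all(e1$scatter$counts >= 0))
  expect_gt(sum(e1$scatter$counts), 0)
})

test_that("zero activity yields a zero estimate; tiny budgets are rejected", {
  ph <- small_phantom(3)
  geom <- small_geometry()
  zero <- spect_volume(ph$tc$data * 0, ph$tc$voxel_mm)
  est <- simulate_scatter(zero, ph$mu_map, 140, energy_window(140), geom,
                          collimator_model(), mc_config(photons = 1e4, seed = 1))
  expect_true(all(est$scatter$counts == 0))
  expect_error(simulate_scatter(ph$tc, ph$mu_map, 140, energy_window(140),
                                geom, collimator_model(),
                                mc_config(photons = 500, seed = 1)),
               "budget")
})

test_that("the estimator is linear: doubling activity doubles scatter", {
  ph <- small_phantom(3)
  geom <- small_geometry()
  coll <- collimator_model()
  run <- function(act, seed) sum(simulate_scatter(
    act, ph$mu_map, 140, energy_window(140), geom, coll,
    mc_config(photons = 3e4, seed = seed))$scatter$counts)
  act2 <- spect_volume(2 * ph$tc$data, ph$tc$voxel_mm)
  t1 <- vapply(1:6, function(s) run(ph$tc, s), numeric(1))
  t2 <- vapply(1:6, function(s) run(act2, 100 + s), numeric(1))
  se <- sqrt(stats::var(t2) / 6 + 4 * stats::var(t1) / 6)
  expect_lt(abs(mean(t2) - 2 * mean(t1)), 3 * se + 1e-9)
})

test_that("single scatter of 140 keV cannot be scored in the Tl window", {
  ph <- small_phantom(3)
  geom <- small_geometry()
  coll <- collimator_model()
  # ideal resolution, one scatter order: kinematically empty estimate
  est1 <- simulate_scatter(ph$tc, ph$mu_map, 140, energy_window(72), geom,
                           coll, mc_config(photons = 5e4, max_order = 1,
                                           seed = 5, eres_fwhm140 = 0))
  expect_true(all(est1$scatter$counts == 0))
  est2 <- simulate_scatter(ph$tc, ph$mu_map, 140, energy_window(72), geom,
                           coll, mc_config(photons = 5e4, max_order = 2,
                                           seed = 5, eres_fwhm140 = 0))
  expect_gt(sum(est2$scatter$counts), 0)
})

test_that("down-scatter refuses a kinematically empty configuration", {
  ph <- small_phantom(3)
  expect_error(simulate_downscatter(ph$tc, ph$mu_map, energy_window(72),
                                    small_geometry(), collimator_model(),
                                    mc_config(photons = 1e4, max_order = 1)),
               "max_order >= 2")
})

test_that("per-bin variance of the estimate scales as 1/budget", {
  ph <- small_phantom(3)
  geom <- small_geometry()
  coll <- collimator_model()
  est <- function(budget, seed) simulate_downscatter(
    ph$tc, ph$mu_map, energy_window(72), geom, coll,
    mc_config(photons = budget, seed = seed))$counts
  lo <- sapply(1:20, function(s) est(1e4, s))
  hi <- sapply(1:20, function(s) est(1e5, 1000 + s))
  v_lo <- apply(lo, 1, stats::var)
  v_hi <- apply(hi, 1, stats::var)
  keep <- rowMeans(hi) > stats::quantile(rowMeans(hi), 0.75)
  ratio <- sum(v_lo[keep]) / sum(v_hi[keep])
  expect_gt(ratio, 7)
  expect_lt(ratio, 13)
})

test_that("down-scatter projections are smoother than the Tc primaries", {
  ph <- small_phantom(3)
  geom <- small_geometry()
  coll <- collimator_model()
  ds <- simulate_downscatter(ph$tc, ph$mu_map, energy_window(72), geom, coll,
                             mc_config(photons = 2e5, seed = 3))$counts
  prim <- forward_project(ph$tc, ph$mu_map, geom, coll, 140)$counts
  high_freq_share <- function(img) {
    f <- Mod(stats::fft(img))^2
    n <- nrow(img)
    q <- n / 4
    freq <- pmin(0:(n - 1), n - 0:(n - 1))
    hi <- outer(freq > q, freq > q, `|`)
    sum(f[hi]) / sum(f[-1])  # exclude the DC term
  }
  shares <- vapply(seq_len(dim(ds)[3]), function(v)
    c(high_freq_share(ds[, , v] / max(sum(ds[, , v]), 1e-12)),
      high_freq_share(prim[, , v] / sum(prim[, , v]))), numeric(2))
  expect_lt(mean(shares[1, ]), mean(shares[2, ]))
})

test_that("coarse factor 2 agrees with factor 1 on the mean estimate", {
  # full-size phantom (the smoothness argument concerns the default grid);
  # single large-budget estimates, smoothed to suppress MC noise before
  # comparing the means
  ph <- fixture("phantom3", function()
    build_cardiac_phantom(cardiac_phantom_spec(3)))
  geom <- spect_geometry()
  coll <- collimator_model()
  one <- function(coarse, seed) simulate_scatter(
    ph$tc, ph$mu_map, 140, energy_window(140), geom, coll,
    mc_config(photons = 1e6, coarse = coarse, seed = seed))$scatter$counts
  sm <- function(p) {
    k <- stats::dnorm(-6:6, sd = 2); k <- k / sum(k)
    for (v in seq_len(dim(p)[3])) {
      m <- p[, , v]
      m <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
      m <- t(apply(m, 1, function(row) stats::filter(row, k, circular = TRUE)))
      p[, , v] <- m
    }
    p
  }
  s1 <- sm(one(1, 1)); s2 <- sm(one(2, 11))
  expect_lt(sqrt(mean((s1 - s2)^2)) / sqrt(mean(s1^2)), 0.05)
  # totals agree even more tightly
  expect_lt(abs(sum(s1) - sum(s2)) / sum(s1), 0.03)
})
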