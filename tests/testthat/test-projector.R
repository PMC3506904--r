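# System model: rotation, adjointness, count conservation, attenuation and
# the incremental Gaussian diffusion collimator model.

test_that("rotation is exact for multiples of 90 degrees and the identity", {
  set.seed(3)
  v <- array(runif(16^3), c(16, 16, 16))
  expect_identical(rotate_volume(v, 0), v)
  r <- v
  for (i in 1:4) r <- rotate_volume(r, 90)
  expect_identical(r, v)
  expect_identical(rotate_volume(rotate_volume(v, 180), 180), v)
})

test_that("rotation conserves intensity for compact interior objects", {
  # a smooth compact blob away from the border
  co <- seq_len(32) - 16.5
  blob <- exp(-outer(co^2, co^2, `+`) / (2 * 4^2))
  v <- array(rep(blob, 8), c(32, 32, 8))
  for (ang in c(17.3, 45, 101.8, 263)) {
    r <- rotate_volume(v, ang)
    expect_lt(abs(sum(r) - sum(v)) / sum(v), 0.005)
  }
})

test_that("back projection is the exact adjoint of forward projection", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- c(16, 20, 24)[seed]
    nv <- c(5, 8, 12)[seed]
    geom <- spect_geometry(n_views = nv, radius_mm = n * 6.6,
                           det_pixels = c(n, n), pixel_mm = 6.6)
    coll <- collimator_model(3.8, 0.0445)
    x <- array(runif(n^3), c(n, n, n))
    mu <- array(runif(n^3) * 0.15, c(n, n, n))
    y <- array(runif(n * n * nv), c(n, n, nv))
    Ax <- forward_project(spect_volume(x, 6.6), mu, geom, coll)$counts
    Aty <- back_project(y, mu, geom, coll)
    lhs <- sum(Ax * y); rhs <- sum(x * Aty)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("counts are conserved without attenuation and a delta PSF", {
  n <- 24
  geom <- spect_geometry(n_views = 8, radius_mm = 120, det_pixels = c(n, n),
                         pixel_mm = 6.6)
  coll0 <- collimator_model(0, 0)
  x <- array(0, c(n, n, n)); x[8:16, 8:16, 8:16] <- runif(9^3)
  p <- forward_project(spect_volume(x, 6.6), array(0, c(n, n, n)),
                       geom, coll0)$counts
  per_view <- apply(p, 3, sum)
  expect_true(all(abs(per_view - sum(x)) / sum(x) < 0.005))
})

test_that("a slab attenuates a point source by the Beer-Lambert factor", {
  n <- 24; vox <- 5
  geom <- spect_geometry(n_views = 1, radius_mm = 100, det_pixels = c(n, n),
                         pixel_mm = vox, angles_deg = 0)
  coll0 <- collimator_model(0, 0)
  x <- array(0, c(n, n, n)); x[12, 2, 12] <- 1
  mu <- array(0, c(n, n, n)); mu[, 3:22, ] <- 0.15  # 20 planes x 0.5 cm = 10 cm
  tot <- sum(forward_project(spect_volume(x, vox), mu, geom, coll0)$counts)
  expect_equal(tot, exp(-1.5), tolerance = 1e-6)
})

test_that("the projected PSF width follows intercept + slope * distance", {
  n <- 64; vox <- 2
  coll <- collimator_model(3.8, 0.0445)
  for (radius in c(80, 140)) {
    geom <- spect_geometry(n_views = 1, radius_mm = radius,
                           det_pixels = c(n, n), pixel_mm = vox,
                           angles_deg = 0)
    x <- array(0, c(n, n, n))
    cx <- (n + 1) / 2  # odd-index centre voxel nearest the rotation axis
    x[32, 32, 32] <- 1
    p <- forward_project(spect_volume(x, vox), array(0, c(n, n, n)),
                         geom, coll)$counts[, , 1]
    prof <- rowSums(p)
    mu1 <- sum(prof * seq_len(n)) / sum(prof)
    sigma_px <- sqrt(sum(prof * (seq_len(n) - mu1)^2) / sum(prof))
    fwhm_mm <- sigma_px * vox * 2 * sqrt(2 * log(2))
    d <- radius - (32 - (n + 1) / 2) * vox  # source plane to collimator face
    expect_equal(fwhm_mm, 3.8 + 0.0445 * d, tolerance = 0.02)
  }
})

test_that("plane-by-plane diffusion equals a one-shot blur for one plane", {
  n <- 48; vox <- 3
  geom <- spect_geometry(n_views = 1, radius_mm = 120, det_pixels = c(n, n),
                         pixel_mm = vox, angles_deg = 0)
  coll <- collimator_model(3.8, 0.0445)
  x <- array(0, c(n, n, n))
  # a single emitting plane holding a smooth compact source
  co <- seq_len(n) - (n + 1) / 2
  x[, 10, ] <- exp(-outer(co^2, co^2, `+`) / (2 * 5^2))
  p <- forward_project(spect_volume(x, vox), array(0, c(n, n, n)),
                       geom, coll)$counts[, , 1]
  # one-shot reference: continuous Gaussian integrated over pixel bins
  d <- 120 - (10 - (n + 1) / 2) * vox
  sigma <- (3.8 + 0.0445 * d) / (2 * sqrt(2 * log(2))) / vox
  r <- ceiling(5 * sigma)
  # bin-integrated Gaussian with Sheppard's correction so the reference
  # kernel's discrete variance equals sigma^2
  k <- diff(stats::pnorm(seq(-r - 0.5, r + 0.5), sd = sqrt(sigma^2 - 1 / 12)))
  k <- k / sum(k)
  blur1 <- function(m) {
    out <- m * 0
    for (i in seq(-r, r))
      out <- out + k[i + r + 1] *
        rbind(matrix(0, max(0, -i), n),
              m[max(1, 1 + i):min(n, n + i), , drop = FALSE],
              matrix(0, max(0, i), n))
    out
  }
  ref <- t(blur1(t(blur1(x[, 10, ]))))
  expect_lt(sqrt(mean((p - ref)^2)) / sqrt(mean(ref^2)), 0.01)
  # the accumulated incremental variance is exact (source variance + blur)
  src <- rowSums(x[, 10, ]); i <- seq_len(n)
  vsrc <- sum(src * (i - sum(src * i) / sum(src))^2) / sum(src)
  prof <- rowSums(p)
  m1 <- sum(prof * i) / sum(prof)
  expect_equal(sum(prof * (i - m1)^2) / sum(prof), vsrc + sigma^2,
               tolerance = 1e-3)
})

test_that("sensitivity maps behave with and without attenuation", {
  n <- 24
  geom <- spect_geometry(n_views = 8, radius_mm = 120, det_pixels = c(n, n),
                         pixel_mm = 6.6)
  coll0 <- collimator_model(0, 0)
  mu0 <- array(0, c(n, n, n))
  s0 <- sensitivity_map(geom, mu0, coll0)
  inner <- s0[8:16, 8:16, 8:16]
  # proportional to the view count on average; bilinear resampling wobbles
  # pointwise (strongest checkerboarding at exactly diagonal view angles)
  expect_true(all(abs(inner - 8) / 8 < 0.15))
  expect_equal(mean(inner), 8, tolerance = 5e-3)
  mu <- array(0.1, c(n, n, n))
  s1 <- sensitivity_map(geom, mu, coll0)
  expect_true(all(s1 < s0 + 1e-12))
  expect_true(all(s1[4:20, 4:20, 4:20] > 0))
  # subset sensitivities sum to the full sensitivity
  subs <- lapply(1:4, function(i) seq(i, 8, by = 4))
  ssum <- Reduce(`+`, lapply(subs, function(v)
    sensitivity_map(geom, mu, coll0, subset = v)))
  expect_equal(ssum, s1, tolerance = 1e-12)
})

test_that("zero projections back-project to a zero volume", {
  n <- 16
  geom <- spect_geometry(n_views = 4, radius_mm = 80, det_pixels = c(n, n),
                         pixel_mm = 6.6)
  z <- back_project(array(0, c(n, n, 4)), array(0.1, c(n, n, n)), geom,
                    collimator_model())
  expect_true(all(z == 0))
})

test_that("geometry violations are rejected with diagnostics", {
  n <- 16
  geom <- spect_geometry(n_views = 4, radius_mm = 80, det_pixels = c(n, n),
                         pixel_mm = 6.6)
  coll <- collimator_model()
  expect_error(forward_project(spect_volume(array(1, c(n, n, n)), 6.6),
                               array(0, c(n, n, 8)), geom, coll),
               "3-D|match")
  tight <- spect_geometry(n_views = 4, radius_mm = 40, det_pixels = c(n, n),
                          pixel_mm = 6.6)
  expect_error(forward_project(spect_volume(array(1, c(n, n, n)), 6.6),
                               array(0, c(n, n, n)), tight, coll),
               "radius")
  expect_error(spect_geometry(n_views = 4, angles_deg = c(0, 90, 45, 135)),
               "increasing")
})
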