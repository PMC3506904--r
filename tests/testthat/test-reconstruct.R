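# OS-EM: MLEM equivalence, fixed point, monotone data fit, non-negativity,
# post-filter behaviour and the dual-isotope orchestration plumbing.

toy_system <- function(n = 16, nv = 8, seed = 1) {
  set.seed(seed)
  geom <- spect_geometry(n_views = nv, radius_mm = n * 6.6,
                         det_pixels = c(n, n), pixel_mm = 6.6)
  coll <- collimator_model(3.8, 0.0445)
  labels <- array(0L, c(n, n, n))
  labels[5:12, 5:12, 5:12] <- 1L
  mu_map <- attenuation_map(labels, 6.6)
  x <- array(0, c(n, n, n))
  x[6:11, 6:11, 6:11] <- 1 + runif(6^3)
  list(geom = geom, coll = coll, mu_map = mu_map,
       mu = mu_volume(mu_map, 140), x = x, n = n, nv = nv)
}

test_that("OS-EM with one subset reproduces a reference MLEM recursion", {
  s <- toy_system()
  y <- forward_project(spect_volume(s$x, 6.6), s$mu, s$geom, s$coll)$counts
  ps <- projection_set(y, s$geom, energy_window(140))
  cfg <- recon_config(iterations = 5, subsets = 1, scatter_iters = 0,
                      postfilter_cm = 0, seed = 1L)
  ours <- osem(ps, s$mu_map, s$geom, s$coll, cfg, scatter = "none")
  # reference: classic MLEM written directly from the recursion
  sens <- sensitivity_map(s$geom, s$mu, s$coll)
  fp1 <- forward_project(spect_volume(array(1, dim(s$x)), 6.6), s$mu,
                         s$geom, s$coll)$counts
  eps <- 1e-10 * mean(y)
  xr <- array(sum(y) / sum(fp1), dim(s$x))
  for (it in 1:5) {
    fp <- forward_project(spect_volume(xr, 6.6), s$mu, s$geom, s$coll)$counts
    xr <- xr * back_project(y / (fp + eps), s$mu, s$geom, s$coll) /
      pmax(sens, 1e-12)
  }
  expect_lt(max(abs(ours$volume$data - xr)) / max(xr), 1e-10)
})

test_that("a consistent uniform estimate is a fixed point of the update", {
  s <- toy_system(seed = 2)
  x0 <- array(0.7, c(s$n, s$n, s$n))
  y <- forward_project(spect_volume(x0, 6.6), s$mu, s$geom, s$coll)$counts
  ps <- projection_set(y, s$geom, energy_window(140))
  cfg <- recon_config(iterations = 1, subsets = 1, scatter_iters = 0,
                      postfilter_cm = 0, seed = 1L)
  out <- osem(ps, s$mu_map, s$geom, s$coll, cfg, scatter = "none")
  # one full update is the identity wherever the system sees the voxel
  seen <- sensitivity_map(s$geom, s$mu, s$coll) > 1e-6
  expect_lt(max(abs(out$volume$data[seen] - 0.7)) / 0.7, 1e-8)
})

test_that("disabled scatter equals a provider that always returns zero", {
  s <- toy_system(seed = 3)
  y <- forward_project(spect_volume(s$x, 6.6), s$mu, s$geom, s$coll)$counts
  ps <- projection_set(y, s$geom, energy_window(140))
  cfg0 <- recon_config(iterations = 3, subsets = 4, scatter_iters = 0,
                       postfilter_cm = 0.9, seed = 9L)
  a <- osem(ps, s$mu_map, s$geom, s$coll, cfg0, scatter = "mc")
  b <- osem(ps, s$mu_map, s$geom, s$coll, cfg0, scatter = "none")
  d <- osem(ps, s$mu_map, s$geom, s$coll, cfg0, scatter = "none",
            additive = array(0, dim(y)))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(b$volume$data, d$volume$data)
})

test_that("KL data fit is non-increasing on noise-free data", {
  n <- 32
  geom <- spect_geometry(n_views = 16, radius_mm = 130, det_pixels = c(n, n),
                         pixel_mm = 6.6)
  coll <- collimator_model()
  ph <- small_phantom(3)
  mu <- mu_volume(ph$mu_map, 140)
  y <- forward_project(ph$tc, mu, geom, coll)$counts
  ps <- projection_set(y, geom, energy_window(140))
  cfg <- recon_config(iterations = 8, subsets = 4, scatter_iters = 0,
                      postfilter_cm = 0, seed = 1L, track_fit = TRUE)
  res <- osem(ps, ph$mu_map, geom, coll, cfg, scatter = "none")
  kl <- vapply(res$log, `[[`, numeric(1), "kl")
  expect_equal(length(kl), 8)
  expect_true(all(diff(kl) <= 1e-6 * abs(kl[-length(kl)]) + 1e-9))
  expect_true(all(res$volume$data >= 0))
})

test_that("dual reconstruction without Tc activity equals a single-isotope run", {
  ph <- small_phantom(3)
  geom <- small_geometry()
  coll <- collimator_model()
  y_tl <- forward_project(ph$tl, mu_volume(ph$mu_map, 72), geom, coll)$counts
  tl_ps <- projection_set(add_poisson_noise(y_tl, 2e5, seed = 8L), geom,
                          energy_window(72), meta = list(scale = 1))
  tc_ps <- projection_set(array(0, dim(y_tl)), geom, energy_window(140),
                          meta = list(scale = 1))
  tc_cfg <- recon_config(iterations = 2, subsets = 4, scatter_iters = 1,
                         photons = 2e3, seed = 1L)
  tl_cfg <- recon_config(iterations = 2, subsets = 4, scatter_iters = 1,
                         photons = 2e3, seed = 2L)
  dual <- reconstruct_dual(tc_ps, tl_ps, ph$mu_map, geom, coll, tc_cfg,
                           tl_cfg, ds_mc = mc_config(photons = 2e3, seed = 3L))
  single <- osem(tl_ps, ph$mu_map, geom, coll, tl_cfg)
  expect_true(all(dual$downscatter == 0))
  expect_identical(dual$tl$data, single$volume$data)
  # per-iteration logs cover every iteration
  expect_equal(length(dual$log$tl), tl_cfg$iterations)
})

test_that("dual reconstruction validates geometry compatibility", {
  ph <- small_phantom(3)
  geom <- small_geometry()
  other <- small_geometry(n_views = 8)
  z16 <- array(0, c(32, 32, 16)); z8 <- array(0, c(32, 32, 8))
  tc_ps <- projection_set(z16, geom, energy_window(140))
  tl_ps <- projection_set(z8, other, energy_window(72))
  expect_error(reconstruct_dual(tc_ps, tl_ps, ph$mu_map, geom,
                                collimator_model(), recon_config(),
                                recon_config()),
               "share the acquisition geometry")
})

test_that("the Gaussian post-filter preserves totals and its nominal width", {
  n <- 48; vox <- 3
  v <- array(0, c(n, n, n)); v[24, 24, 24] <- 1
  sv <- spect_volume(v, vox)
  expect_identical(gaussian_postfilter(sv, 0)$data, v)
  f <- gaussian_postfilter(sv, 0.9)
  expect_lt(abs(sum(f$data) - 1), 1e-3)
  prof <- apply(f$data, 1, sum)
  mu1 <- sum(prof * seq_len(n)) / sum(prof)
  sigma_px <- sqrt(sum(prof * (seq_len(n) - mu1)^2) / sum(prof))
  fwhm_cm <- sigma_px * vox * 2 * sqrt(2 * log(2)) / 10
  expect_equal(fwhm_cm, 0.9, tolerance = 0.03)
})

test_that("down-scatter correction improves the dual-study Tl-201 contrast", {
  # paired runs on the shared full-size study: with the correction the
  # anterior-defect contrast must beat the uncorrected reconstruction
  corrected <- acc_contrast(acc_tl_optimised()$volume, "defect")
  uncorr <- osem(acc_sim()$tl_dual, acc_phantom()$mu_map,
                 acc_study()$geometry, acc_study()$collimator,
                 recon_config(scatter_iters = 2, photons = 1e5, seed = 2L))
  expect_gt(corrected, acc_contrast(uncorr$volume, "defect"))
})

test_that("reconstructions are bitwise reproducible under a fixed seed", {
  ph <- small_phantom(3)
  geom <- small_geometry()
  coll <- collimator_model()
  y <- forward_project(ph$tl, mu_volume(ph$mu_map, 72), geom, coll)$counts
  ps <- projection_set(add_poisson_noise(y, 1e5, seed = 4L), geom,
                       energy_window(72))
  cfg <- recon_config(iterations = 3, subsets = 4, scatter_iters = 2,
                      photons = 2e3, seed = 6L)
  r1 <- osem(ps, ph$mu_map, geom, coll, cfg)
  r2 <- osem(ps, ph$mu_map, geom, coll, cfg)
  expect_identical(r1$volume$data, r2$volume$data)
})
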