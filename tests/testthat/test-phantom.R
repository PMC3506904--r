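# Digital phantoms: organ painting, defect carving, activity bookkeeping,
# Jaszczak-style insert, study simulation and Poisson noise.

test_that("cardiac phantom reproduces the configured activity ratios", {
  ph <- small_phantom(3)
  tc <- ph$tc$data
  liver_val <- unique(tc[ph$organs == 3])
  myo_healthy <- ph$organs == 4
  for (m in ph$defect_masks) myo_healthy <- myo_healthy & !m
  myo_val <- unique(tc[myo_healthy])
  expect_equal(liver_val, 90)
  expect_equal(myo_val, 180)
  expect_equal(liver_val / myo_val, 0.5)  # hot-liver configuration
})

test_that("defects carry the configured residual fraction per isotope", {
  ph <- small_phantom(3)  # anterior 20% in both; septal 40% reversible (Tl)
  ant <- ph$defect_masks[[which(vapply(ph$defect_masks, attr, "", "wall") == "anterior")]]
  sept <- ph$defect_masks[[which(vapply(ph$defect_masks, attr, "", "wall") == "septal")]]
  expect_true(all(ph$tc$data[ant] == 0.2 * 180))
  expect_true(all(ph$tl$data[ant] == 0.2 * 50))
  expect_true(all(ph$tl$data[sept] == 0.4 * 50))
  expect_true(all(ph$tc$data[sept] == 180))  # reversible: full Tc activity
})

test_that("zero activities give zero volumes and organs partition the body", {
  zero <- c(myocardium = 0, ventricle = 0, lung = 0, liver = 0, body = 0)
  ph <- small_phantom(3, tc_activity = zero, tl_activity = zero)
  expect_true(all(ph$tc$data == 0))
  expect_true(all(ph$tl$data == 0))
  # organ labels are one label per voxel by construction; activity totals
  # equal sum over organs of concentration x voxel count
  ph3 <- small_phantom(3)
  counts <- table(factor(ph3$organs, levels = 0:6))
  act <- ph3$spec$tc_activity
  expected <- act[["body"]] * (counts[["1"]] + counts[["6"]]) +
    act[["lung"]] * counts[["2"]] + act[["liver"]] * counts[["3"]] +
    act[["myocardium"]] * counts[["4"]] + act[["ventricle"]] * counts[["5"]]
  ant <- ph3$defect_masks[[1]]
  expected <- expected - sum(ant) * act[["myocardium"]] * (1 - 0.2)
  expect_equal(sum(ph3$tc$data), as.numeric(expected))
})

test_that("attenuation map orders lung < soft tissue < bone", {
  ph <- small_phantom(3)
  mu <- mu_volume(ph$mu_map, 140)
  mu_lung <- unique(mu[ph$organs == 2])
  mu_soft <- unique(mu[ph$organs == 1])
  mu_bone <- unique(mu[ph$organs == 6])
  expect_lt(mu_lung, mu_soft)
  expect_lt(mu_soft, mu_bone)
  expect_true(all(mu[ph$organs == 0] == 0))
})

test_that("overlapping organ ellipsoids are rejected with a diagnostic", {
  spec <- small_phantom_spec(3)
  spec$geometry$liver_center <- spec$geometry$lung_centers[[2]]
  expect_error(build_cardiac_phantom(spec), "ambiguous|more than one organ")
})

test_that("Jaszczak insert concentrations follow the MBq filling scheme", {
  spec <- jaszczak_phantom_spec(grid = 32, voxel_mm = 6.6,
                                cylinder_radius_mm = 90,
                                cylinder_height_mm = 150,
                                geometry = list(heart_semi = c(30, 30, 40),
                                                wall_mm = 9))
  ph <- build_jaszczak_phantom(spec)
  ant <- ph$defect_masks[[which(vapply(ph$defect_masks, attr, "", "wall") == "anterior")]]
  healthy <- ph$organs == 4
  for (m in ph$defect_masks) healthy <- healthy & !m
  conc_myo <- unique(ph$tl$data[healthy])
  conc_def <- unique(ph$tl$data[ant])
  # concentration ratio from 0.04 vs 8.18 MBq scaled by compartment volumes
  expect_equal(conc_def / conc_myo,
               (0.04 / sum(ant)) / (8.18 / sum(healthy)))
  # reversible anterior defect: full myocardial concentration in Tc
  expect_equal(unique(ph$tc$data[ant]), unique(ph$tc$data[healthy]))
})

test_that("degenerate and insert-free cylinders behave as specified", {
  expect_error(jaszczak_phantom_spec(cylinder_radius_mm = 0), "degenerate")
  spec <- jaszczak_phantom_spec(grid = 32, voxel_mm = 6.6,
                                cylinder_radius_mm = 80,
                                cylinder_height_mm = 140, insert = FALSE,
                                background_concentration = 2.5)
  ph <- build_jaszczak_phantom(spec)
  expect_setequal(unique(as.integer(ph$organs)), c(0L, 1L))
  expect_equal(sum(ph$tl$data), 2.5 * sum(ph$organs == 1))
})

test_that("study simulation is reproducible and additive in the cross-talk", {
  ph <- small_phantom(3)
  study <- small_study()
  s1 <- simulate_study(ph, study, seed = 5L)
  s2 <- simulate_study(ph, study, seed = 5L)
  expect_identical(s1$tc$counts, s2$tc$counts)
  expect_identical(s1$tl_dual$counts, s2$tl_dual$counts)
  expect_identical(s1$tl_pure$counts, s2$tl_pure$counts)
  # the dual Tl window holds strictly more expected counts than pure Tl
  expect_true(all(s1$expected$tl_dual >= s1$expected$tl_pure))
  expect_gt(sum(s1$expected$tl_dual), sum(s1$expected$tl_pure))

  # without Tc activity there is no cross-talk source
  zero <- c(myocardium = 0, ventricle = 0, lung = 0, liver = 0, body = 0)
  ph0 <- small_phantom(3, tc_activity = zero)
  s0 <- simulate_study(ph0, study, seed = 5L)
  expect_identical(s0$expected$tl_dual, s0$expected$tl_pure)
  expect_true(all(s0$expected$downscatter == 0))
})

test_that("Poisson noise hits the target totals with unit Fano factor", {
  expect_arr <- array(50, c(16, 16, 4))  # 51200 expected counts
  tot <- replicate(40, sum(add_poisson_noise(expect_arr, sum(expect_arr),
                                             seed = sample.int(1e6, 1))))
  expect_lt(abs(mean(tot) - sum(expect_arr)) / sum(expect_arr), 0.01)
  # Fano factor over independent bins at >= 1e4 aggregate expected counts
  set.seed(11)
  draws <- vapply(1:200, function(i)
    add_poisson_noise(expect_arr, sum(expect_arr), seed = i)[1, 1, 1],
    numeric(1))
  fano <- stats::var(draws) / mean(draws)
  expect_gt(fano, 0.8)
  expect_lt(fano, 1.25)
  # scale bookkeeping and determinism
  ps <- projection_set(expect_arr, small_geometry(4, 16), energy_window(140))
  out <- add_poisson_noise(ps, sum(expect_arr), seed = 3L)
  expect_equal(out$meta$scale, 1)
  expect_identical(out$counts,
                   add_poisson_noise(ps, sum(expect_arr), seed = 3L)$counts)
  expect_error(add_poisson_noise(expect_arr * 0, 100, seed = 1L), "all-zero")
})

test_that("collapsing projections preserves counts and pixel bookkeeping", {
  set.seed(2)
  g <- spect_geometry(n_views = 4, radius_mm = 300, det_pixels = c(128, 128),
                      pixel_mm = 3.3)
  p <- projection_set(array(rpois(128 * 128 * 4, 5), c(128, 128, 4)), g,
                      energy_window(140))
  c2 <- collapse_projections(p, 2)
  expect_equal(dim(c2$counts), c(64, 64, 4))
  expect_identical(sum(c2$counts), sum(p$counts))
  expect_equal(c2$geometry$pixel_mm, 6.6)
  expect_identical(collapse_projections(p, 1), p)
  u <- array(3, c(8, 8, 2))
  expect_true(all(collapse_projections(u, 2) == 12))
  expect_error(collapse_projections(array(0, c(9, 9, 2)), 2), "divide")
})
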