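# Shared fixtures: a small scaled-down cardiac phantom and geometry for fast
# unit tests, plus lazily built (memoised) heavy objects reused by the
# acceptance tests: the full Phantom-3 dual-isotope study and its
# reconstructions.

small_geometry <- function(n_views = 16, n = 32, voxel = 6.6, radius = 130)
  spect_geometry(n_views = n_views, radius_mm = radius,
                 det_pixels = c(n, n), pixel_mm = voxel)

small_phantom_spec <- function(phantom = 3, ...) {
  cardiac_phantom_spec(phantom, grid = 32, voxel_mm = 6.6, ...,
    geometry = list(
      body_semi    = c(95, 65, 100),
      lung_semi    = c(22, 28, 36),
      lung_centers = list(c(-47, -5, 20), c(47, -5, 20)),
      liver_center = c(34, 13, -44),
      liver_semi   = c(33, 24, 24),
      heart_center = c(0, -17, 27),
      heart_semi   = c(22, 22, 29),
      wall_mm      = 8,
      base_cut_mm  = 10,
      defect_z_mm  = -7,
      spine_center_y = 42,
      spine_radius = 7))
}

small_phantom <- function(phantom = 3, ...)
  build_cardiac_phantom(small_phantom_spec(phantom, ...))

small_study <- function(mc_photons = 5e3)
  study_spec(n_views = 16, radius_mm = 130, det_pixels = c(32, 32),
             pixel_mm = 6.6, mc_photons = mc_photons)

# ---------------------------------------------------------------------------
# memoised heavy fixtures (full 64^3 Phantom-3 study, shared by the
# acceptance tests so each expensive object is built once per test run)
# ---------------------------------------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

acc_phantom <- function()
  fixture("phantom3", function() build_cardiac_phantom(cardiac_phantom_spec(3)))

acc_study <- function() fixture("study", function() study_spec())

acc_sim <- function()
  fixture("sim", function() simulate_study(acc_phantom(), acc_study(), seed = 42L))

# Tc-99m reconstruction with the optimised parameters (2 scatter updates,
# 1e5 photons, 10 iterations, 8 subsets, coarse 2, 0.9 cm post-filter)
acc_tc_recon <- function()
  fixture("tc_recon", function()
    osem(acc_sim()$tc, acc_phantom()$mu_map, acc_study()$geometry,
         acc_study()$collimator, recon_config(seed = 1L)))

# down-scatter estimates from the reconstructed Tc volume at three budgets,
# rescaled to Tl-window count units
acc_downscatter <- function(photons)
  fixture(paste0("ds_", format(photons, scientific = FALSE)), function() {
    sim <- acc_sim()
    ds <- simulate_downscatter(acc_tc_recon()$volume, acc_phantom()$mu_map,
                               tl_window = sim$tl_dual$window,
                               acc_study()$geometry, acc_study()$collimator,
                               mc_config(photons = photons, seed = 3L))
    ds$counts * sim$tl_dual$meta$scale / sim$tc$meta$scale
  })

# Tl-201 reconstruction of the dual study against a given down-scatter term
acc_tl_recon <- function(ds_counts, scatter_iters, photons, seed = 2L) {
  osem(acc_sim()$tl_dual, acc_phantom()$mu_map, acc_study()$geometry,
       acc_study()$collimator,
       recon_config(scatter_iters = scatter_iters, photons = photons,
                    seed = seed),
       additive = ds_counts)
}

# cached Tl-201 reconstructions of the dual study: the optimised parameter
# set (2 scatter updates, 1e5 photons, 1e6 down-scatter photons) and the
# reference grid of 10-update/1e6-photon runs against each down-scatter budget
acc_tl_optimised <- function()
  fixture("tl_opt", function()
    acc_tl_recon(acc_downscatter(1e6), scatter_iters = 2, photons = 1e5))

acc_tl_reference <- function(ds_budget)
  fixture(paste0("tl_ref_", format(ds_budget, scientific = FALSE)), function()
    acc_tl_recon(acc_downscatter(ds_budget), scatter_iters = 10,
                 photons = 1e6))

acc_contrast <- function(volume, what = c("defect", "lv")) {
  what <- match.arg(what)
  # the 6.6 mm defect mask holds fewer pixels than the requested ROI area;
  # the documented equal-area trim applies
  ct <- suppressWarnings(contrast_analysis(volume, acc_phantom(),
                                           defect = "anterior"))
  if (what == "defect") ct$contrast_myocardium_defect
  else ct$contrast_myocardium_lv
}
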