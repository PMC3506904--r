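#' OS-EM reconstruction with intermittent Monte Carlo scatter correction
#'
#' Ordered-subsets expectation maximisation with the rotation-based system
#' model, an additive projection-domain scatter term refreshed by the Monte
#' Carlo engine during the first few iterations only (intermittent scatter
#' modelling), a 3-D Gaussian post-filter, and the three-step dual-isotope
#' orchestration: (1) Tc-99m reconstruction, (2) Monte Carlo Tc-99m
#' down-scatter simulation into the Tl-201 window from the reconstructed
#' Tc-99m image, (3) Tl-201 reconstruction with the down-scatter estimate
#' added to the Tl-201 self-scatter estimate.
#'
#' @name reconstruct
NULL

#' Reconstruction configuration
#'
#' @param iterations Number of OS-EM iterations (default 10).
#' @param subsets Number of ordered subsets (default 8); must divide the view
#'   count.
#' @param scatter_iters How many leading iterations refresh the Monte Carlo
#'   self-scatter estimate (default 2). Iteration 1 runs with zero
#'   self-scatter; the estimate is recomputed from the current volume at the
#'   start of iterations 2..(1 + scatter_iters) and frozen afterwards. 0
#'   disables self-scatter correction entirely.
#' @param photons Photon budget for each self-scatter update (default 1e5).
#' @param coarse,max_order,eres_fwhm140 Monte Carlo engine settings (see
#'   [mc_config()]).
#' @param postfilter_cm FWHM of the isotropic 3-D Gaussian post-filter in cm
#'   (default 0.9; 0 disables).
#' @param seed Integer seed; per-update seeds are derived from it.
#' @param track_fit If `TRUE`, log the Kullback-Leibler data fit after every
#'   iteration (costs one extra forward projection per iteration).
#' @return A `recon_config` object.
#' @export
recon_config <- function(iterations = 10, subsets = 8, scatter_iters = 2,
                         photons = 1e5, coarse = 2, max_order = 3,
                         postfilter_cm = 0.9, seed = 1L,
                         eres_fwhm140 = 0.099, track_fit = FALSE) {
  stopifnot(iterations >= 1, subsets >= 1,
            scatter_iters >= 0, scatter_iters <= iterations,
            postfilter_cm >= 0)
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 scatter_iters = as.integer(scatter_iters),
                 photons = photons, coarse = as.integer(coarse),
                 max_order = as.integer(max_order),
                 postfilter_cm = postfilter_cm, seed = as.integer(seed),
                 eres_fwhm140 = eres_fwhm140, track_fit = isTRUE(track_fit)),
            class = "recon_config")
}

# bit-reversed ordering of 0..(n-1) for angularly balanced subset visits
.bit_reverse_order <- function(n) {
  bits <- ceiling(log2(max(n, 2)))
  key <- vapply(0:(n - 1), function(i) {
    b <- as.integer(intToBits(i))[seq_len(bits)]
    sum(b * 2^((bits - 1):0))
  }, numeric(1))
  order(key, seq_len(n))
}

#' OS-EM reconstruction of one projection set
#'
#' Multiplicative update per subset S:
#' x <- x * \[A_S' (y_S / (A_S x + s_S + eps))\] / A_S' 1,
#' where s is the additive projection-domain scatter term: the Monte Carlo
#' self-scatter estimate (refreshed intermittently per `config`) plus any
#' frozen `additive` term (e.g. a down-scatter estimate). The final volume is
#' post-filtered with the configured 3-D Gaussian.
#'
#' @param projections A [projection_set()] with a `window` (its centre also
#'   serves as the emission energy for self-scatter simulation).
#' @param mu_map A labelled [attenuation_map()].
#' @param geometry,collimator As in [forward_project()].
#' @param config A [recon_config()].
#' @param scatter `"mc"` for Monte Carlo self-scatter correction, `"none"`
#'   to disable (equivalent to `scatter_iters = 0`).
#' @param additive Optional frozen additive projection term (array or
#'   [projection_set()]), e.g. a down-scatter estimate. May be zero.
#' @return An `osem_result`: list with `volume` (post-filtered
#'   [spect_volume()]), `volume_raw`, `scatter` (the final self-scatter
#'   term), and `log` (one row per iteration: KL data fit when tracked,
#'   scatter-update flag, seed used).
#' @export
osem <- function(projections, mu_map, geometry, collimator, config,
                 scatter = c("mc", "none"), additive = NULL) {
  scatter <- match.arg(scatter)
  stopifnot(inherits(projections, "projection_set"),
            inherits(config, "recon_config"))
  y <- projections$counts
  if (any(y < 0)) stop("projection bins must be non-negative")
  nview <- geometry$n_views
  if (nview %% config$subsets != 0)
    stop("subsets (", config$subsets, ") must divide the view count (",
         nview, ")")
  window <- projections$window
  if (is.null(window)) stop("projections must carry an energy window")
  energy <- window$center_kev
  voxel_mm <- geometry$pixel_mm
  d <- c(geometry$det_pixels[1], geometry$det_pixels[1], geometry$det_pixels[2])
  mu <- mu_volume(mu_map, energy)

  S <- config$subsets
  subset_views <- lapply(seq_len(S), function(i) seq(i, nview, by = S))
  subset_order <- .bit_reverse_order(S)
  sens <- lapply(subset_views, function(v)
    back_project(array(1, c(d[1], d[3], length(v))), mu, geometry, collimator,
                 subset = v))

  s_add <- if (is.null(additive)) 0 else as_projection_array(additive)
  eps <- 1e-10 * mean(y)
  if (eps <= 0) eps <- 1e-12

  # uniform initial estimate scaled so total forward counts match the data
  x <- array(1, d)
  f1 <- cpp_project(x, mu, d, geometry$angles_deg, geometry$radius_mm,
                    voxel_mm, collimator$fwhm0_mm, collimator$slope, TRUE)
  x[] <- sum(y) / max(sum(f1 + s_add), eps)

  s_self <- array(0, dim(y))
  log <- vector("list", config$iterations)
  for (it in seq_len(config$iterations)) {
    updated <- FALSE
    seed_it <- config$seed + it
    if (scatter == "mc" && config$scatter_iters > 0 &&
        it >= 2 && it <= 1 + config$scatter_iters) {
      est <- simulate_scatter(spect_volume(x, voxel_mm), mu_map, energy,
                              window, geometry, collimator,
                              mc_config(photons = config$photons,
                                        coarse = config$coarse,
                                        max_order = config$max_order,
                                        seed = seed_it,
                                        eres_fwhm140 = config$eres_fwhm140))
      s_self <- est$scatter$counts
      updated <- TRUE
    }
    s_tot <- s_self + s_add
    for (si in subset_order) {
      v <- subset_views[[si]]
      fp <- cpp_project(x, mu, d, geometry$angles_deg[v], geometry$radius_mm,
                        voxel_mm, collimator$fwhm0_mm, collimator$slope, TRUE)
      ratio <- y[, , v, drop = FALSE] / (fp + s_tot[, , v, drop = FALSE] + eps)
      bp <- cpp_project(ratio, mu, d, geometry$angles_deg[v],
                        geometry$radius_mm, voxel_mm, collimator$fwhm0_mm,
                        collimator$slope, FALSE)
      x <- x * bp / pmax(sens[[si]], 1e-12)
    }
    kl <- NA_real_
    if (config$track_fit) {
      fp <- cpp_project(x, mu, d, geometry$angles_deg, geometry$radius_mm,
                        voxel_mm, collimator$fwhm0_mm, collimator$slope, TRUE)
      yhat <- fp + s_tot + eps
      kl <- sum(ifelse(y > 0, y * log(y / yhat), 0) - y + yhat)
    }
    log[[it]] <- list(iteration = it, kl = kl, scatter_updated = updated,
                      seed = seed_it)
  }
  raw <- spect_volume(x, voxel_mm)
  vol <- if (config$postfilter_cm > 0)
    gaussian_postfilter(raw, config$postfilter_cm) else raw
  structure(list(volume = vol, volume_raw = raw,
                 scatter = s_self, log = log, config = config),
            class = "osem_result")
}

#' @export
print.osem_result <- function(x, ...) {
  cat(sprintf("<osem_result> %d iterations x %d subsets, total %.4g\n",
              x$config$iterations, x$config$subsets, sum(x$volume$data)))
  invisible(x)
}

#' Three-step dual-isotope reconstruction
#'
#' Step 1 reconstructs the Tc-99m window with attenuation, collimator and
#' Monte Carlo self-scatter correction. Step 2 simulates Tc-99m down-scatter
#' into the Tl-201 window from the reconstructed (post-filtered) Tc-99m
#' volume. Step 3 reconstructs the Tl-201 window with the frozen down-scatter
#' estimate added to the Tl-201 self-scatter term. When both projection sets
#' carry the per-window count scales written by [simulate_study()], the
#' down-scatter estimate is rescaled by their ratio so it is expressed in
#' Tl-window count units.
#'
#' @param tc_projections,tl_projections [projection_set()]s sharing one
#'   geometry (the Tc-99m window and the Tl-201 window of the dual study).
#' @param mu_map,geometry,collimator As in [osem()].
#' @param tc_config,tl_config [recon_config()]s for steps 1 and 3.
#' @param ds_mc [mc_config()] for the down-scatter simulation (default 1e6
#'   photons).
#' @param downscatter Set `FALSE` to skip step 2 (no cross-talk correction).
#' @return A `dual_recon_result`: `tc` and `tl` (post-filtered volumes),
#'   `downscatter` (the estimate used), `log` (per-iteration logs of both
#'   reconstructions), `tc_result`/`tl_result`.
#' @export
reconstruct_dual <- function(tc_projections, tl_projections, mu_map, geometry,
                             collimator, tc_config, tl_config,
                             ds_mc = mc_config(photons = 1e6),
                             downscatter = TRUE) {
  stopifnot(inherits(tc_projections, "projection_set"),
            inherits(tl_projections, "projection_set"))
  if (!isTRUE(all.equal(tc_projections$geometry$angles_deg,
                        tl_projections$geometry$angles_deg)) ||
      any(tc_projections$geometry$det_pixels != tl_projections$geometry$det_pixels))
    stop("Tc and Tl projection sets must share the acquisition geometry")

  tc_res <- osem(tc_projections, mu_map, geometry, collimator, tc_config)

  ds <- NULL
  ds_counts <- array(0, dim(tl_projections$counts))
  if (downscatter) {
    ds <- simulate_downscatter(tc_res$volume, mu_map,
                               tl_window = tl_projections$window,
                               geometry, collimator, ds_mc)
    cal <- 1
    if (!is.null(tl_projections$meta$scale) &&
        !is.null(tc_projections$meta$scale))
      cal <- tl_projections$meta$scale / tc_projections$meta$scale
    ds_counts <- ds$counts * cal
  }

  tl_res <- osem(tl_projections, mu_map, geometry, collimator, tl_config,
                 additive = ds_counts)

  structure(list(tc = tc_res$volume, tl = tl_res$volume,
                 downscatter = ds_counts,
                 log = list(tc = tc_res$log, tl = tl_res$log),
                 tc_result = tc_res, tl_result = tl_res),
            class = "dual_recon_result")
}

#' @export
print.dual_recon_result <- function(x, ...) {
  cat("<dual_recon_result> Tc-99m and Tl-201 volumes",
      sprintf("(down-scatter total %.4g)\n", sum(x$downscatter)))
  invisible(x)
}

#' 3-D Gaussian post-filter
#'
#' Separable isotropic Gaussian smoothing; sigma = FWHM / 2.3548 converted to
#' voxels. Totals of interior sources are preserved (normalised kernel).
#'
#' @param volume A [spect_volume()] or 3-D array.
#' @param fwhm_cm Filter FWHM in cm (0 = identity).
#' @param voxel_mm Voxel size; taken from the volume when available.
#' @return Same type as the input.
#' @export
gaussian_postfilter <- function(volume, fwhm_cm, voxel_mm = NULL) {
  arr <- as_volume_array(volume)
  if (is.null(voxel_mm)) {
    if (!inherits(volume, "spect_volume"))
      stop("voxel_mm is required for plain arrays")
    voxel_mm <- volume$voxel_mm
  }
  stopifnot(fwhm_cm >= 0)
  sigma_px <- fwhm_cm * 10 / 2.3548200450309493 / voxel_mm
  out <- cpp_gauss3d(arr, dim(arr), sigma_px)
  if (inherits(volume, "spect_volume")) spect_volume(pmax(out, 0), voxel_mm)
  else out
}
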