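#' Accelerated Monte Carlo scatter estimation
#'
#' A forced-detection photon-transport engine that estimates self-scatter
#' projections for the isotope being reconstructed and Tc-99m to Tl-201
#' down-scatter projections. Acceleration levers: the input image and
#' attenuation map are folded onto a coarse grid (scatter is smooth), the
#' expected contribution of every Compton interaction is scored into every
#' view instead of waiting for analog detection, and the photon budget is
#' configurable. Estimates are normalised so that the engine's unscattered
#' (order-0) projections match the analytic forward projector's totals,
#' making the scatter term unit-consistent with the OS-EM denominator
#' A x + s.
#'
#' @name mcscatter
NULL

#' Monte Carlo engine configuration
#'
#' @param photons Photon budget: number of emitted source photons per
#'   estimate (not per view). Estimation calls require >= 1000.
#' @param coarse Coarse-grid folding factor (integer >= 1); must divide the
#'   grid dimensions.
#' @param max_order Maximum Compton scatter order tracked (>= 1; down-scatter
#'   needs >= 2 because single scatter from 140 keV cannot reach the Tl-201
#'   window).
#' @param seed Integer seed; identical seeds give bitwise-identical
#'   estimates.
#' @param eres_fwhm140 Fractional detector energy resolution (FWHM) at
#'   140 keV; 0 for an ideal detector.
#' @return An `mc_config` object.
#' @export
mc_config <- function(photons = 1e5, coarse = 2, max_order = 3, seed = 1L,
                      eres_fwhm140 = 0.099) {
  coarse <- as.integer(coarse)
  stopifnot(photons >= 1, coarse >= 1, max_order >= 1, eres_fwhm140 >= 0)
  structure(list(photons = photons, coarse = coarse,
                 max_order = as.integer(max_order), seed = as.integer(seed),
                 eres_fwhm140 = eres_fwhm140),
            class = "mc_config")
}

#' Fold a volume onto a coarse grid
#'
#' Activity volumes are folded by block sums (total activity preserved
#' exactly); attenuation maps by block means.
#'
#' @param volume A [spect_volume()] or 3-D array.
#' @param factor Integer folding factor dividing every grid dimension.
#' @param mode `"sum"` (activity) or `"mean"` (attenuation coefficients).
#' @return Same type as the input, with voxel size multiplied by `factor`.
#' @export
coarse_fold <- function(volume, factor, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  arr <- as_volume_array(volume)
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(volume)
  d <- dim(arr)
  if (any(d %% factor != 0))
    stop("factor ", factor, " does not divide the grid dimensions ",
         paste(d, collapse = "x"))
  nd <- d %/% factor
  dim(arr) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(arr, c(2, 4, 6), sum)
  if (mode == "mean") out <- out / factor^3
  if (inherits(volume, "spect_volume"))
    spect_volume(out, volume$voxel_mm * factor)
  else out
}

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# expand a coarse projection stack to the full detector grid, conserving
# totals (each coarse bin spread uniformly over its factor^2 fine bins)
.upsample_views <- function(coarse, factor, det_pixels) {
  d <- dim(coarse)
  out <- array(0, c(det_pixels[1], det_pixels[2], d[3]))
  iu <- rep(seq_len(d[1]), each = factor)
  iv <- rep(seq_len(d[2]), each = factor)
  out[] <- coarse[iu, iv, , drop = FALSE] / factor^2
  out
}

#' Estimate scatter projections with the Monte Carlo engine
#'
#' Emission sites are sampled proportional to the activity on the coarse
#' grid; photons are tracked through the attenuation map (Woodcock tracking,
#' interaction type chosen by the Compton/photoelectric components, Compton
#' angles from the Klein-Nishina distribution); after every scatter up to
#' `max_order` the expected detected contribution is scored into every view
#' (Klein-Nishina density towards the detector x transmission along the exit
#' path at the scattered energy x window acceptance), and unscattered
#' (order-0) scores accumulate a primary estimate used for normalisation.
#'
#' @param activity A [spect_volume()] or 3-D array: the emitting
#'   distribution (a phantom volume or a current reconstruction).
#' @param mu_map A labelled [attenuation_map()] (needed to rescale the
#'   Compton/photoelectric components with energy).
#' @param emission_kev Source photon energy (keV).
#' @param window [energy_window()] the scatter estimate is scored in.
#' @param geometry,collimator As in [forward_project()].
#' @param mc An [mc_config()].
#' @param emission_window Acceptance window used for the order-0
#'   normalisation scores; defaults to a 15% window at the emission energy.
#' @return List with `scatter` (a [projection_set()] congruent with the
#'   target geometry), `primary` (normalised order-0 estimate, array),
#'   `kappa` (the applied normalisation factor).
#' @export
simulate_scatter <- function(activity, mu_map, emission_kev, window,
                             geometry, collimator, mc,
                             emission_window = energy_window(emission_kev)) {
  stopifnot(inherits(mc, "mc_config"), inherits(window, "energy_window"),
            inherits(mu_map, "attenuation_map"))
  arr <- as_volume_array(activity)
  voxel_mm <- if (inherits(activity, "spect_volume")) activity$voxel_mm
              else geometry$pixel_mm
  d <- dim(arr)
  check_projector_geometry(d, voxel_mm, geometry)
  if (any(arr < 0)) arr <- pmax(arr, 0)
  meta <- list(budget = mc$photons, seed = mc$seed, coarse = mc$coarse,
               emission_kev = emission_kev, max_order = mc$max_order)
  if (sum(arr) == 0) {
    z <- array(0, c(geometry$det_pixels, geometry$n_views))
    return(list(scatter = projection_set(z, geometry, window, meta),
                primary = z, kappa = 0))
  }
  if (mc$photons < 1e3)
    stop("photon budget ", mc$photons, " is below the minimum of 1000 for ",
         "estimation calls")
  if (any(d %% mc$coarse != 0))
    stop("coarse factor ", mc$coarse, " does not divide the grid dimensions")

  act_c <- coarse_fold(arr, mc$coarse, "sum")
  muC <- coarse_fold(.mu_component_volume(mu_map, "compton"), mc$coarse, "mean")
  muP <- coarse_fold(.mu_component_volume(mu_map, "photo"), mc$coarse, "mean")
  dc <- dim(act_c)

  res <- with_seed(mc$seed,
    cpp_mc_scatter(act_c, muC, muP, dc, voxel_mm * mc$coarse,
                   geometry$angles_deg, emission_kev, mc$photons,
                   mc$max_order, window$lo_kev, window$hi_kev,
                   emission_window$lo_kev, emission_window$hi_kev,
                   mc$eres_fwhm140, window$center_kev))

  scatter <- .upsample_views(res$scatter, mc$coarse, geometry$det_pixels)
  primary <- .upsample_views(res$primary, mc$coarse, geometry$det_pixels)

  # collimator blur at a representative (orbit-radius) distance
  sig_px <- (collimator$fwhm0_mm + collimator$slope * geometry$radius_mm) /
    2.3548200450309493 / geometry$pixel_mm
  scatter <- cpp_blur_views(scatter, dim(scatter), sig_px^2)

  # unit consistency: order-0 Monte Carlo totals match the analytic projector
  analytic <- forward_project(arr, mu_map, geometry, collimator,
                              energy_kev = emission_kev)$counts
  ptot <- sum(primary)
  kappa <- if (ptot > 0) sum(analytic) / ptot else 0
  scatter <- scatter * kappa
  stopifnot(all(is.finite(scatter)), all(scatter >= 0))
  list(scatter = projection_set(scatter, geometry, window, meta),
       primary = primary * kappa, kappa = kappa)
}

# component attenuation volume at the 140 keV reference energy
.mu_component_volume <- function(map, component) {
  mu_by_label <- c(0, vapply(map$materials, function(m)
    mu_at(m, 140, component, map$table), numeric(1)))
  array(mu_by_label[map$labels + 1L], dim(map$labels))
}

#' Estimate Tc-99m down-scatter into the Tl-201 window
#'
#' Specialises [simulate_scatter()] to 140 keV emission scored in the Tl-201
#' window. Because a single Compton scatter of a 140 keV photon cannot fall
#' below 90.4 keV, at least two scatter orders are required; requesting
#' `max_order = 1` is an error.
#'
#' @param tc_reconstruction The reconstructed Tc-99m volume
#'   ([spect_volume()] or array).
#' @param mu_map,geometry,collimator As in [simulate_scatter()].
#' @param tl_window The Tl-201 acceptance window (default 15% at 72 keV).
#' @param mc An [mc_config()].
#' @return A [projection_set()]: the down-scatter estimate.
#' @export
simulate_downscatter <- function(tc_reconstruction, mu_map,
                                 tl_window = energy_window(72),
                                 geometry, collimator, mc) {
  if (mc$max_order < 2)
    stop("down-scatter requires max_order >= 2: a single Compton scatter of ",
         "a 140 keV photon retains at least 90.4 keV and cannot reach the ",
         "Tl-201 window, so an order-1 estimate is kinematically empty")
  simulate_scatter(tc_reconstruction, mu_map, 140, tl_window, geometry,
                   collimator, mc,
                   emission_window = energy_window(140))$scatter
}
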