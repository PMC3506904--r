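#' Rotation-based projector with attenuation and collimator modelling
#'
#' The SPECT system model: for every view the volume is resampled in-plane so
#' that the detector normal aligns with a grid axis, then detector-parallel
#' planes are swept from far to near, accumulating plane activity weighted by
#' the transmission accumulated so far, with each plane's contribution
#' incrementally blurred so its total blur at the detector equals the
#' distance-dependent Gaussian collimator PSF. The back projector is the
#' exact adjoint (same interpolation and kernels in reverse order), which is
#' what OS-EM requires.
#'
#' @name projector
NULL

#' Acquisition geometry for a circular-orbit parallel-hole SPECT scan
#'
#' @param n_views Number of projection views (>= 1).
#' @param arc_deg Total orbit arc in degrees (default 360).
#' @param radius_mm Orbit radius: distance from the rotation axis to the
#'   collimator face. Must exceed the imaged object's half-extent.
#' @param det_pixels Detector grid (bins transaxial, bins axial).
#' @param pixel_mm Detector pixel size in mm. The projector requires it to
#'   equal the volume voxel size.
#' @param angles_deg Optional explicit view angles (degrees, strictly
#'   increasing within one revolution); default evenly spaced over `arc_deg`.
#' @return A `spect_geometry` object.
#' @export
spect_geometry <- function(n_views = 64, arc_deg = 360, radius_mm = 250,
                           det_pixels = c(64, 64), pixel_mm = 6.6,
                           angles_deg = NULL) {
  stopifnot(n_views >= 1, radius_mm > 0, pixel_mm > 0,
            length(det_pixels) == 2L, all(det_pixels >= 1))
  if (is.null(angles_deg))
    angles_deg <- arc_deg * (seq_len(n_views) - 1) / n_views
  if (length(angles_deg) != n_views)
    stop("angles_deg must have length n_views")
  if (n_views > 1 && any(diff(angles_deg) <= 0))
    stop("view angles must be strictly increasing")
  if (max(angles_deg) - min(angles_deg) >= 360)
    stop("view angles must lie within one revolution")
  structure(list(n_views = as.integer(n_views),
                 angles_deg = as.numeric(angles_deg),
                 radius_mm = radius_mm,
                 det_pixels = as.integer(det_pixels),
                 pixel_mm = pixel_mm),
            class = "spect_geometry")
}

#' @export
print.spect_geometry <- function(x, ...) {
  cat(sprintf("<spect_geometry> %d views over %.0f deg, radius %.0f mm, %dx%d @ %.2f mm\n",
              x$n_views, diff(range(x$angles_deg)) * x$n_views / (x$n_views - 1),
              x$radius_mm, x$det_pixels[1], x$det_pixels[2], x$pixel_mm))
  invisible(x)
}

#' Distance-dependent Gaussian collimator model
#'
#' PSF full width at half maximum grows linearly with source-to-collimator
#' distance d: FWHM(d) = intercept + slope * d. Defaults are representative
#' low-energy high-resolution (LEHR) parallel-hole figures.
#'
#' @param fwhm0_mm PSF FWHM at the collimator face, mm (>= 0).
#' @param slope FWHM growth per mm of distance (dimensionless, >= 0).
#' @return A `collimator_model` object.
#' @export
collimator_model <- function(fwhm0_mm = 3.8, slope = 0.0445) {
  stopifnot(fwhm0_mm >= 0, slope >= 0)
  structure(list(fwhm0_mm = fwhm0_mm, slope = slope),
            class = "collimator_model")
}

#' @export
print.collimator_model <- function(x, ...) {
  cat(sprintf("<collimator_model> FWHM(d) = %.2f + %.4f d mm\n",
              x$fwhm0_mm, x$slope))
  invisible(x)
}

#' A stack of projection views plus its acquisition metadata
#'
#' @param counts Numeric array (bins-u, bins-v, views), non-negative.
#' @param geometry The [spect_geometry()] the views were acquired with.
#' @param window Optional [energy_window()] the data belong to.
#' @param meta Optional list of provenance fields (seed, scale, totals, ...).
#' @return A `projection_set` object.
#' @export
projection_set <- function(counts, geometry, window = NULL, meta = list()) {
  if (length(dim(counts)) != 3L)
    stop("expected a 3-D projection array, got ", length(dim(counts)), " axes")
  stopifnot(inherits(geometry, "spect_geometry"))
  d <- dim(counts)
  if (d[3] != geometry$n_views)
    stop("projection stack has ", d[3], " views but geometry declares ",
         geometry$n_views)
  if (any(d[1:2] != geometry$det_pixels))
    stop("projection grid does not match geometry det_pixels")
  structure(list(counts = counts, geometry = geometry, window = window,
                 meta = meta),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$counts)
  w <- if (is.null(x$window)) "no window" else
    sprintf("%.0f keV window", x$window$center_kev)
  cat(sprintf("<projection_set> %dx%d x %d views, %s, total %.4g\n",
              d[1], d[2], d[3], w, sum(x$counts)))
  invisible(x)
}

as_projection_array <- function(x) {
  if (inherits(x, "projection_set")) return(x$counts)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a projection_set or 3-D array")
}

# resolve mu input (attenuation_map or plain array) at an energy
resolve_mu <- function(mu, energy_kev, dims) {
  m <- if (inherits(mu, "attenuation_map")) {
    if (is.null(energy_kev))
      stop("energy_kev is required when mu is an attenuation_map")
    mu_volume(mu, energy_kev)
  } else if (is.array(mu) && length(dim(mu)) == 3L) {
    mu
  } else stop("mu must be an attenuation_map or a 3-D array of 1/cm values")
  if (!all(dim(m) == dims))
    stop("attenuation grid ", paste(dim(m), collapse = "x"),
         " does not match activity grid ", paste(dims, collapse = "x"))
  m
}

check_projector_geometry <- function(dims, voxel_mm, geometry) {
  if (dims[1] != dims[2])
    stop("the projector requires a square in-plane grid")
  if (geometry$det_pixels[1] != dims[1] || geometry$det_pixels[2] != dims[3])
    stop("detector grid must equal the volume grid (bins-u = nx, bins-v = nz)")
  if (abs(geometry$pixel_mm - voxel_mm) > 1e-9)
    stop("detector pixel size must equal the voxel size")
  half_extent <- dims[1] * voxel_mm / 2
  if (geometry$radius_mm <= half_extent)
    stop("orbit radius ", geometry$radius_mm,
         " mm is smaller than the object half-extent")
}

#' Rotate a volume in-plane
#'
#' Resamples the volume so the detector normal for a view at `angle_deg`
#' aligns with the +y grid axis. Bilinear in-plane interpolation with zero
#' fill; exact index permutation for multiples of 90 degrees.
#'
#' @param volume A [spect_volume()] or 3-D array (square in-plane).
#' @param angle_deg Rotation angle in degrees.
#' @param adjoint If `TRUE`, apply the exact adjoint of the resampling.
#' @return Object of the same type as the input.
#' @export
rotate_volume <- function(volume, angle_deg, adjoint = FALSE) {
  arr <- as_volume_array(volume)
  d <- dim(arr)
  if (d[1] != d[2]) stop("rotation requires a square in-plane grid")
  out <- cpp_rotate(arr, d, angle_deg, adjoint)
  if (inherits(volume, "spect_volume")) spect_volume(pmax(out, 0), volume$voxel_mm)
  else out
}

#' Forward project an activity volume
#'
#' Computes the expected primary (unscattered) counts per detector bin for
#' every view: rotation, far-to-near plane sweep with multiplicative
#' attenuation per plane step (each plane's own emission attenuated over half
#' its thickness), and incremental Gaussian diffusion so the accumulated blur
#' of each plane matches the collimator PSF at that plane's distance.
#'
#' @param activity A [spect_volume()] (or 3-D array with `voxel_mm` given via
#'   geometry pixel size).
#' @param mu An [attenuation_map()] (rescaled to `energy_kev`) or a 3-D array
#'   of linear attenuation coefficients (1/cm) matching the activity grid.
#' @param geometry A [spect_geometry()].
#' @param collimator A [collimator_model()].
#' @param energy_kev Photon energy for attenuation scaling (required when
#'   `mu` is an attenuation_map).
#' @param subset Optional integer view indices to project (default all).
#' @return A [projection_set()] of expected counts (array if `subset` given).
#' @export
forward_project <- function(activity, mu, geometry, collimator,
                            energy_kev = NULL, subset = NULL) {
  arr <- as_volume_array(activity)
  voxel_mm <- if (inherits(activity, "spect_volume")) activity$voxel_mm
              else geometry$pixel_mm
  d <- dim(arr)
  check_projector_geometry(d, voxel_mm, geometry)
  m <- resolve_mu(mu, energy_kev, d)
  idx <- if (is.null(subset)) seq_len(geometry$n_views) else as.integer(subset)
  p <- cpp_project(arr, m, d, geometry$angles_deg[idx], geometry$radius_mm,
                   voxel_mm, collimator$fwhm0_mm, collimator$slope, TRUE)
  if (is.null(subset))
    projection_set(p, geometry,
                   window = if (!is.null(energy_kev)) energy_window(energy_kev) else NULL)
  else p
}

#' Back project a set of views
#'
#' Exact adjoint of [forward_project()] as implemented: the same
#' interpolation, attenuation weighting and diffusion kernels applied in
#' reverse order.
#'
#' @param projections A [projection_set()] or 3-D array (bins-u, bins-v,
#'   n-views-selected).
#' @param mu,geometry,collimator,energy_kev As in [forward_project()].
#' @param subset Optional integer view indices corresponding to the slices of
#'   `projections` (default all views).
#' @param voxel_mm Voxel size; defaults to the geometry pixel size.
#' @return 3-D array (the adjoint image).
#' @export
back_project <- function(projections, mu, geometry, collimator,
                         energy_kev = NULL, subset = NULL,
                         voxel_mm = geometry$pixel_mm) {
  p <- as_projection_array(projections)
  d <- c(dim(p)[1], dim(p)[1], dim(p)[2])
  check_projector_geometry(d, voxel_mm, geometry)
  idx <- if (is.null(subset)) seq_len(geometry$n_views) else as.integer(subset)
  if (dim(p)[3] != length(idx))
    stop("projection stack has ", dim(p)[3], " views but ", length(idx),
         " were selected")
  m <- resolve_mu(mu, energy_kev, d)
  cpp_project(p, m, d, geometry$angles_deg[idx], geometry$radius_mm,
              voxel_mm, collimator$fwhm0_mm, collimator$slope, FALSE)
}

#' OS-EM sensitivity image
#'
#' Back projection of unit views for the chosen subset; the normalisation
#' denominator of the OS-EM update. Strictly positive inside the field of
#' view.
#'
#' @inheritParams back_project
#' @return 3-D array.
#' @export
sensitivity_map <- function(geometry, mu, collimator, energy_kev = NULL,
                            subset = NULL, voxel_mm = geometry$pixel_mm) {
  idx <- if (is.null(subset)) seq_len(geometry$n_views) else as.integer(subset)
  ones <- array(1, c(geometry$det_pixels[1], geometry$det_pixels[2], length(idx)))
  back_project(ones, mu, geometry, collimator, energy_kev, subset = idx,
               voxel_mm = voxel_mm)
}
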