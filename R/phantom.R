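#' Digital phantoms for dual-isotope myocardial perfusion SPECT
#'
#' A stylised parametric torso (body ellipsoid, two lung ellipsoids, liver
#' ellipsoid, spine cylinder and a half-ellipsoid left-ventricular
#' myocardial shell with cavity) standing in for the NURBS-based cardiac
#' torso anatomy, plus a Jaszczak-style cylinder with a cardiac insert.
#' Both produce paired Tc-99m/Tl-201 activity volumes, a labelled
#' attenuation map and organ labels, and feed the dual-isotope study
#' simulator.
#'
#' @name phantom
NULL

# organ label codes
.ORGAN_LEVELS <- c(air = 0L, body = 1L, lung = 2L, liver = 3L,
                   myocardium = 4L, ventricle = 5L, spine = 6L)

#' Describe a myocardial perfusion defect
#'
#' A defect is an angular sector of the myocardial shell (short-axis polar
#' coordinates) with reduced activity. Wall directions in this phantom:
#' anterior = -y, inferior = +y, septal = +x, lateral = -x.
#'
#' @param wall One of `"anterior"`, `"inferior"`, `"septal"`, `"lateral"`.
#' @param fraction Residual activity as a fraction of myocardial activity
#'   (0-1), e.g. 0.2 for a 20% defect.
#' @param isotope Which activity volume carries the defect: `"both"`
#'   (irreversible), `"tl"` (reversible: present at stress only) or `"tc"`.
#' @param extent_deg Angular extent of the sector in degrees (> 0).
#' @param extent_mm Axial extent in mm (> 0).
#' @return A `defect_spec` object.
#' @export
defect_spec <- function(wall = c("anterior", "inferior", "septal", "lateral"),
                        fraction, isotope = c("both", "tl", "tc"),
                        extent_deg = 60, extent_mm = 20) {
  wall <- match.arg(wall)
  isotope <- match.arg(isotope)
  stopifnot(fraction >= 0, fraction <= 1, extent_deg > 0, extent_mm > 0)
  structure(list(wall = wall, fraction = fraction, isotope = isotope,
                 extent_deg = extent_deg, extent_mm = extent_mm),
            class = "defect_spec")
}

# Table-1 activity sets (relative concentration per voxel) and defects
.TL_ACTIVITY <- c(myocardium = 50, ventricle = 3, lung = 2, liver = 3, body = 3)
.TC_ACTIVITY <- list(
  hot_liver  = c(myocardium = 180, ventricle = 6, lung = 18, liver = 90, body = 6),
  very_hot_liver = c(myocardium = 95, ventricle = 3, lung = 9, liver = 189, body = 3))

.table1_defects <- function(phantom) {
  switch(as.character(phantom),
    "1" = list(defect_spec("anterior", 0.2, "both"),
               defect_spec("septal",   0.4, "both")),
    "2" = list(defect_spec("anterior", 0.4, "tl"),
               defect_spec("inferior", 0.2, "tl")),
    "3" = list(defect_spec("anterior", 0.2, "both"),
               defect_spec("septal",   0.4, "tl")),
    "4" = list(defect_spec("anterior", 0.4, "tl"),
               defect_spec("inferior", 0.2, "both")),
    stop("phantom must be 1, 2, 3 or 4"))
}

#' Specification of the stylised cardiac torso phantom
#'
#' The default activity configurations and defect lists reproduce the four
#' standard study outcomes (hot or very hot liver in the Tc-99m data,
#' reversible and irreversible anterior/inferior/septal defects at 20-40% of
#' myocardial activity); geometry parameters are a versioned stylised
#' anatomy.
#'
#' @param phantom Configuration number 1-4 selecting the activity set and
#'   defect list; ignored when `tc_activity`, `tl_activity` and `defects`
#'   are all supplied.
#' @param grid Voxels per axis (length 1 or 3), default 64.
#' @param voxel_mm Isotropic voxel size in mm, default 6.6.
#' @param tc_activity,tl_activity Named vectors of relative per-voxel
#'   activity concentrations for organs `myocardium`, `ventricle`, `lung`,
#'   `liver`, `body`.
#' @param defects List of [defect_spec()] objects.
#' @param geometry Named list of organ geometry parameters (mm, relative to
#'   the grid centre); see the package vignette. Override individual entries
#'   via this argument.
#' @return A `phantom_spec` object.
#' @export
cardiac_phantom_spec <- function(phantom = 3, grid = 64, voxel_mm = 6.6,
                                 tc_activity = NULL, tl_activity = NULL,
                                 defects = NULL, geometry = list()) {
  if (length(grid) == 1L) grid <- rep(grid, 3L)
  stopifnot(length(grid) == 3L, all(grid >= 8), voxel_mm > 0)
  if (is.null(tc_activity))
    tc_activity <- if (phantom %in% c(1, 3)) .TC_ACTIVITY$hot_liver
                   else .TC_ACTIVITY$very_hot_liver
  if (is.null(tl_activity)) tl_activity <- .TL_ACTIVITY
  if (is.null(defects)) defects <- .table1_defects(phantom)
  for (a in list(tc_activity, tl_activity)) {
    if (!all(c("myocardium", "ventricle", "lung", "liver", "body") %in% names(a)))
      stop("activity vectors need myocardium, ventricle, lung, liver, body")
    if (any(a < 0)) stop("relative activities must be non-negative")
  }
  geo <- list(
    body_semi    = c(190, 130, 205),
    lung_semi    = c(45, 60, 75),
    lung_centers = list(c(-95, -10, 40), c(95, -10, 40)),
    liver_center = c(70, 25, -85),
    liver_semi   = c(70, 50, 50),
    heart_center = c(0, -35, 55),
    heart_semi   = c(45, 45, 60),
    wall_mm      = 12,
    base_cut_mm  = 20,
    defect_z_mm  = -15,
    spine_center_y = 85,
    spine_radius = 15
  )
  geo[names(geometry)] <- geometry
  if (geo$wall_mm <= 0) stop("myocardial wall thickness must be positive")
  if (any(geo$heart_semi <= geo$wall_mm))
    stop("wall thickness leaves no ventricular cavity")
  structure(list(kind = "cardiac", phantom = phantom,
                 grid = as.integer(grid), voxel_mm = voxel_mm,
                 tc_activity = tc_activity, tl_activity = tl_activity,
                 defects = defects, geometry = geo),
            class = "phantom_spec")
}

# voxel-centre coordinates in mm relative to the grid centre
.grid_coords <- function(grid, voxel_mm) {
  lapply(seq_len(3), function(a) (seq_len(grid[a]) - (grid[a] + 1) / 2) * voxel_mm)
}

.ellipsoid_mask <- function(co, center, semi) {
  nx <- length(co[[1]]); ny <- length(co[[2]]); nz <- length(co[[3]])
  u2 <- ((co[[1]] - center[1]) / semi[1])^2
  v2 <- ((co[[2]] - center[2]) / semi[2])^2
  w2 <- ((co[[3]] - center[3]) / semi[3])^2
  outer(outer(u2, v2, `+`), w2, `+`) <= 1
}

.wall_angle_deg <- function(wall) {
  switch(wall, anterior = 270, inferior = 90, septal = 0, lateral = 180)
}

#' Build the stylised cardiac torso phantom
#'
#' Paints organ labels onto the voxel grid (rejecting specifications whose
#' organ ellipsoids overlap), fills the per-isotope relative activity
#' concentrations, carves the defects, and derives a labelled attenuation
#' map (soft tissue, lung, bone).
#'
#' @param spec A [cardiac_phantom_spec()].
#' @return A `dualspect_phantom`: list with `tc` and `tl` ([spect_volume()]),
#'   `mu_map` ([attenuation_map()]), `organs` (integer label array),
#'   `defect_masks` (list of logical arrays with wall/fraction/isotope
#'   attributes) and the originating `spec`.
#' @export
build_cardiac_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind == "cardiac")
  g <- spec$grid; geo <- spec$geometry
  co <- .grid_coords(g, spec$voxel_mm)
  body <- .ellipsoid_mask(co, c(0, 0, 0), geo$body_semi)
  lungs <- .ellipsoid_mask(co, geo$lung_centers[[1]], geo$lung_semi) |
           .ellipsoid_mask(co, geo$lung_centers[[2]], geo$lung_semi)
  liver <- .ellipsoid_mask(co, geo$liver_center, geo$liver_semi)
  heart_outer <- .ellipsoid_mask(co, geo$heart_center, geo$heart_semi)
  heart_inner <- .ellipsoid_mask(co, geo$heart_center,
                                 geo$heart_semi - geo$wall_mm)
  zrel <- co[[3]] - geo$heart_center[3]
  below_base <- aperm(array(rep(zrel <= geo$base_cut_mm, each = g[1] * g[2]),
                            g), c(1, 2, 3))
  heart <- heart_outer & below_base
  myo <- heart & !heart_inner
  vent <- heart & heart_inner
  spine <- outer(outer(co[[1]]^2, (co[[2]] - geo$spine_center_y)^2, `+`),
                 rep(0, g[3]), `+`) <= geo$spine_radius^2
  spine <- spine & body

  overlap <- lungs + liver + heart + spine
  if (any(overlap > 1))
    stop("ambiguous phantom: ", sum(overlap > 1),
         " voxels claimed by more than one organ; adjust the geometry")
  if (any((lungs | liver | heart) & !body))
    stop("organ ellipsoids extend outside the body mask")

  organs <- array(.ORGAN_LEVELS[["air"]], g)
  organs[body]  <- .ORGAN_LEVELS[["body"]]
  organs[lungs] <- .ORGAN_LEVELS[["lung"]]
  organs[liver] <- .ORGAN_LEVELS[["liver"]]
  organs[spine] <- .ORGAN_LEVELS[["spine"]]
  organs[myo]   <- .ORGAN_LEVELS[["myocardium"]]
  organs[vent]  <- .ORGAN_LEVELS[["ventricle"]]

  fill_activity <- function(act) {
    a <- array(0, g)
    a[organs == .ORGAN_LEVELS[["body"]] |
      organs == .ORGAN_LEVELS[["spine"]]] <- act[["body"]]
    a[organs == .ORGAN_LEVELS[["lung"]]] <- act[["lung"]]
    a[organs == .ORGAN_LEVELS[["liver"]]] <- act[["liver"]]
    a[organs == .ORGAN_LEVELS[["myocardium"]]] <- act[["myocardium"]]
    a[organs == .ORGAN_LEVELS[["ventricle"]]] <- act[["ventricle"]]
    a
  }
  tc <- fill_activity(spec$tc_activity)
  tl <- fill_activity(spec$tl_activity)

  # angular position of each voxel in the short-axis plane
  xrel <- co[[1]] - geo$heart_center[1]
  yrel <- co[[2]] - geo$heart_center[2]
  ang <- atan2(matrix(yrel, g[1], g[2], byrow = TRUE),
               matrix(xrel, g[1], g[2])) * 180 / pi
  ang <- array(rep(ang, g[3]), g)
  zarr <- aperm(array(rep(zrel, each = g[1] * g[2]), g), c(1, 2, 3))

  defect_masks <- list()
  for (d in spec$defects) {
    a0 <- .wall_angle_deg(d$wall)
    dang <- (ang - a0 + 180) %% 360 - 180
    mask <- myo & abs(dang) <= d$extent_deg / 2 &
      abs(zarr - geo$defect_z_mm) <= d$extent_mm / 2
    if (d$isotope %in% c("both", "tc"))
      tc[mask] <- d$fraction * spec$tc_activity[["myocardium"]]
    if (d$isotope %in% c("both", "tl"))
      tl[mask] <- d$fraction * spec$tl_activity[["myocardium"]]
    attr(mask, "wall") <- d$wall
    attr(mask, "fraction") <- d$fraction
    attr(mask, "isotope") <- d$isotope
    defect_masks[[length(defect_masks) + 1L]] <- mask
  }

  materials <- array(0L, g)
  materials[organs %in% .ORGAN_LEVELS[c("body", "liver", "myocardium",
                                        "ventricle")]] <- 1L  # soft
  materials[organs == .ORGAN_LEVELS[["lung"]]] <- 2L
  materials[organs == .ORGAN_LEVELS[["spine"]]] <- 3L

  structure(list(
    tc = spect_volume(tc, spec$voxel_mm),
    tl = spect_volume(tl, spec$voxel_mm),
    mu_map = attenuation_map(materials, spec$voxel_mm),
    organs = organs,
    defect_masks = defect_masks,
    heart_center_mm = geo$heart_center,
    spec = spec), class = "dualspect_phantom")
}

#' @export
print.dualspect_phantom <- function(x, ...) {
  g <- dim(x$organs)
  cat(sprintf("<dualspect_phantom> %s, %dx%dx%d @ %.2f mm, %d defect(s)\n",
              x$spec$kind, g[1], g[2], g[3], x$spec$voxel_mm,
              length(x$defect_masks)))
  invisible(x)
}

#' Specification of the Jaszczak-style cardiac-insert phantom
#'
#' A water-filled cylinder containing a half-ellipsoid cardiac insert with
#' fillable defects. Compartment activities are stated in MBq and converted
#' to per-voxel concentrations using the voxelised compartment volumes. The
#' defaults reproduce the physical-phantom filling scheme: Tl-201 8.18 MBq
#' myocardium / 0.34 MBq ventricle / 0.04 + 0.04 MBq anterior + inferior
#' defects; Tc-99m 35.96 / 1.25 MBq with a single 0.17 MBq inferior defect
#' (the anterior defect is reversible).
#'
#' @param grid,voxel_mm Grid shape and voxel size, as for
#'   [cardiac_phantom_spec()].
#' @param cylinder_radius_mm,cylinder_height_mm Body cylinder dimensions (mm).
#' @param insert `TRUE` for the cardiac insert, `FALSE` for a uniform
#'   cylinder.
#' @param background_concentration Per-voxel activity of the cylinder water
#'   compartment (both isotopes), default 0.
#' @param tl_mbq,tc_mbq Named numeric vectors of compartment activities in
#'   MBq; names among `myocardium`, `ventricle`, `defect_anterior`,
#'   `defect_inferior`.
#' @param geometry Overrides for the insert geometry (see
#'   [cardiac_phantom_spec()]).
#' @return A `phantom_spec` object of kind `"jaszczak"`.
#' @export
jaszczak_phantom_spec <- function(grid = 64, voxel_mm = 6.6,
                                  cylinder_radius_mm = 108,
                                  cylinder_height_mm = 186,
                                  insert = TRUE,
                                  background_concentration = 0,
                                  tl_mbq = c(myocardium = 8.18, ventricle = 0.34,
                                             defect_anterior = 0.04,
                                             defect_inferior = 0.04),
                                  tc_mbq = c(myocardium = 35.96, ventricle = 1.25,
                                             defect_inferior = 0.17),
                                  geometry = list()) {
  if (length(grid) == 1L) grid <- rep(grid, 3L)
  if (cylinder_radius_mm <= 0 || cylinder_height_mm <= 0)
    stop("degenerate cylinder: radius and height must be positive")
  stopifnot(background_concentration >= 0, all(tl_mbq >= 0), all(tc_mbq >= 0))
  geo <- list(
    heart_center = c(0, 0, 20),
    heart_semi   = c(40, 40, 55),
    wall_mm      = 10,
    base_cut_mm  = 20,
    defect_z_mm  = -10,
    defect_extent_deg = 60,
    defect_extent_mm  = 20
  )
  geo[names(geometry)] <- geometry
  structure(list(kind = "jaszczak", grid = as.integer(grid),
                 voxel_mm = voxel_mm,
                 cylinder_radius_mm = cylinder_radius_mm,
                 cylinder_height_mm = cylinder_height_mm,
                 insert = insert,
                 background_concentration = background_concentration,
                 tl_mbq = tl_mbq, tc_mbq = tc_mbq, geometry = geo),
            class = "phantom_spec")
}

#' Build the Jaszczak-style cardiac-insert phantom
#'
#' @param spec A [jaszczak_phantom_spec()].
#' @return A `dualspect_phantom`, as for [build_cardiac_phantom()]. Activity
#'   values are per-voxel concentrations in MBq per voxel.
#' @export
build_jaszczak_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind == "jaszczak")
  g <- spec$grid; geo <- spec$geometry
  co <- .grid_coords(g, spec$voxel_mm)
  r2 <- outer(co[[1]]^2, co[[2]]^2, `+`)
  in_radius <- array(rep(r2 <= spec$cylinder_radius_mm^2, g[3]), g)
  in_height <- aperm(array(rep(abs(co[[3]]) <= spec$cylinder_height_mm / 2,
                               each = g[1] * g[2]), g), c(1, 2, 3))
  body <- in_radius & in_height
  if (!any(body)) stop("cylinder does not intersect the voxel grid")

  organs <- array(.ORGAN_LEVELS[["air"]], g)
  organs[body] <- .ORGAN_LEVELS[["body"]]
  tc <- array(0, g); tl <- array(0, g)
  tc[body] <- spec$background_concentration
  tl[body] <- spec$background_concentration
  defect_masks <- list()

  if (spec$insert) {
    heart_outer <- .ellipsoid_mask(co, geo$heart_center, geo$heart_semi)
    heart_inner <- .ellipsoid_mask(co, geo$heart_center,
                                   geo$heart_semi - geo$wall_mm)
    zrel <- co[[3]] - geo$heart_center[3]
    below <- aperm(array(rep(zrel <= geo$base_cut_mm, each = g[1] * g[2]), g),
                   c(1, 2, 3))
    heart <- heart_outer & below
    if (any(heart & !body))
      stop("cardiac insert extends outside the cylinder")
    myo <- heart & !heart_inner
    vent <- heart & heart_inner
    organs[myo] <- .ORGAN_LEVELS[["myocardium"]]
    organs[vent] <- .ORGAN_LEVELS[["ventricle"]]

    xrel <- co[[1]] - geo$heart_center[1]
    yrel <- co[[2]] - geo$heart_center[2]
    ang <- atan2(matrix(yrel, g[1], g[2], byrow = TRUE),
                 matrix(xrel, g[1], g[2])) * 180 / pi
    ang <- array(rep(ang, g[3]), g)
    zarr <- aperm(array(rep(zrel, each = g[1] * g[2]), g), c(1, 2, 3))
    walls <- c(defect_anterior = "anterior", defect_inferior = "inferior")
    dmask <- list()
    for (nm in names(walls)) {
      a0 <- .wall_angle_deg(walls[[nm]])
      dang <- (ang - a0 + 180) %% 360 - 180
      m <- myo & abs(dang) <= geo$defect_extent_deg / 2 &
        abs(zarr - geo$defect_z_mm) <= geo$defect_extent_mm / 2
      dmask[[nm]] <- m
    }
    healthy_myo <- myo
    for (m in dmask) healthy_myo <- healthy_myo & !m

    voxel_ml <- 1 # concentrations are MBq per voxel; ratios are what matter
    fill <- function(mbq) {
      a <- array(0, g)
      conc_myo <- if ("myocardium" %in% names(mbq))
        mbq[["myocardium"]] / max(1L, sum(healthy_myo)) / voxel_ml else 0
      a[myo] <- conc_myo
      if ("ventricle" %in% names(mbq))
        a[vent] <- mbq[["ventricle"]] / max(1L, sum(vent)) / voxel_ml
      for (nm in names(dmask)) {
        if (nm %in% names(mbq)) {
          a[dmask[[nm]]] <- mbq[[nm]] / max(1L, sum(dmask[[nm]])) / voxel_ml
        } # compartments absent from the filling keep myocardial activity
      }
      a
    }
    tcin <- fill(spec$tc_mbq); tlin <- fill(spec$tl_mbq)
    tc[heart] <- tcin[heart]; tl[heart] <- tlin[heart]

    for (nm in names(dmask)) {
      m <- dmask[[nm]]
      attr(m, "wall") <- walls[[nm]]
      frac_tl <- if (nm %in% names(spec$tl_mbq) && spec$tl_mbq[["myocardium"]] > 0)
        (spec$tl_mbq[[nm]] / max(1L, sum(m))) /
          (spec$tl_mbq[["myocardium"]] / max(1L, sum(healthy_myo))) else NA_real_
      attr(m, "fraction") <- frac_tl
      attr(m, "isotope") <- if (nm %in% names(spec$tc_mbq)) "both" else "tl"
      defect_masks[[length(defect_masks) + 1L]] <- m
    }
  }

  materials <- array(0L, g)
  materials[organs != .ORGAN_LEVELS[["air"]]] <- 1L
  structure(list(
    tc = spect_volume(tc, spec$voxel_mm),
    tl = spect_volume(tl, spec$voxel_mm),
    mu_map = attenuation_map(materials, spec$voxel_mm,
                             materials = c("water", "lung", "bone")),
    organs = organs,
    defect_masks = defect_masks,
    heart_center_mm = geo$heart_center,
    spec = spec), class = "dualspect_phantom")
}

#' Acquisition protocol for a simulated dual-isotope study
#'
#' Defaults follow the simultaneous stress-Tl-201/rest-Tc-99m protocol: 64
#' views, 64x64 matrix, two 15% windows at 72 and 140 keV, and window totals
#' of 80 (Tl dual), 76 (Tc) and 10 (pure Tl) megacounts scaled by
#' `count_scale`.
#'
#' @param n_views,arc_deg,radius_mm,det_pixels,pixel_mm Geometry, as
#'   [spect_geometry()].
#' @param tc_window,tl_window Energy windows.
#' @param count_scale Global multiplier on the window count targets (use < 1
#'   for quick desk-scale studies).
#' @param tc_counts,tl_dual_counts,tl_pure_counts Target total counts per
#'   window after scaling.
#' @param mc_photons Photon budget for the study's scatter and down-scatter
#'   terms (data generation).
#' @param coarse,max_order,eres_fwhm140 Monte Carlo engine settings for data
#'   generation.
#' @param collimator A [collimator_model()].
#' @return A `study_spec` object.
#' @export
study_spec <- function(n_views = 64, arc_deg = 360, radius_mm = 250,
                       det_pixels = c(64, 64), pixel_mm = 6.6,
                       tc_window = energy_window(140),
                       tl_window = energy_window(72),
                       count_scale = 1,
                       tc_counts = 76e6 * count_scale,
                       tl_dual_counts = 80e6 * count_scale,
                       tl_pure_counts = 10e6 * count_scale,
                       mc_photons = 2e6, coarse = 2, max_order = 3,
                       eres_fwhm140 = 0.099,
                       collimator = collimator_model()) {
  stopifnot(n_views >= 1, tc_counts > 0, tl_dual_counts > 0, tl_pure_counts > 0)
  geometry <- spect_geometry(n_views, arc_deg, radius_mm, det_pixels, pixel_mm)
  structure(list(geometry = geometry, tc_window = tc_window,
                 tl_window = tl_window,
                 targets = c(tc = tc_counts, tl_dual = tl_dual_counts,
                             tl_pure = tl_pure_counts),
                 mc_photons = mc_photons, coarse = coarse,
                 max_order = max_order, eres_fwhm140 = eres_fwhm140,
                 collimator = collimator),
            class = "study_spec")
}

#' Simulate a complete dual-isotope study
#'
#' Generates noise-free expected projections for the Tc-99m window (Tc
#' primaries + Tc self-scatter), the Tl-201 window of the simultaneous dual
#' study (Tl primaries + Tl self-scatter + Tc-99m down-scatter) and a pure
#' Tl-201 study without the down-scatter term; rescales each window to its
#' target totals; and adds Poisson noise. The applied scale factors are
#' recorded in each projection set's `meta` so the down-scatter estimate can
#' be carried between windows during reconstruction.
#'
#' @param phantom A `dualspect_phantom`.
#' @param study A [study_spec()].
#' @param seed Integer seed controlling the scatter simulations and the
#'   Poisson noise.
#' @param components Which datasets to generate (any of `"tc"`, `"tl_dual"`,
#'   `"tl_pure"`); restricting them skips the scatter simulations the others
#'   need without changing the seeds (and hence the data) of those kept.
#' @return List with `projection_set`s `tc`, `tl_dual`, `tl_pure` (requested
#'   ones only), plus `expected` (the noise-free window expectations before
#'   scaling) and `seed`.
#' @export
simulate_study <- function(phantom, study, seed = 1L,
                           components = c("tc", "tl_dual", "tl_pure")) {
  components <- match.arg(components, several.ok = TRUE)
  stopifnot(inherits(phantom, "dualspect_phantom"), inherits(study, "study_spec"))
  geom <- study$geometry
  if (!all(dim(phantom$organs) == c(geom$det_pixels[1], geom$det_pixels[1],
                                    geom$det_pixels[2])))
    stop("phantom grid is incompatible with the study detector grid")
  if (abs(phantom$spec$voxel_mm - geom$pixel_mm) > 1e-9)
    stop("phantom voxel size must match the study pixel size")
  if (study$tl_window$hi_kev > study$tc_window$lo_kev &&
      study$tl_window$lo_kev < study$tc_window$hi_kev)
    stop("energy windows overlap")
  coll <- study$collimator
  mc <- function(s) mc_config(photons = study$mc_photons, coarse = study$coarse,
                              max_order = study$max_order, seed = s,
                              eres_fwhm140 = study$eres_fwhm140)

  need_tc <- "tc" %in% components
  need_dual <- "tl_dual" %in% components
  need_tl <- need_dual || "tl_pure" %in% components

  e_tc <- e_tl_pure <- e_tl_dual <- s_ds <- NULL
  if (need_tc) {
    a_tc <- forward_project(phantom$tc, phantom$mu_map, geom, coll,
                            energy_kev = study$tc_window$center_kev)$counts
    s_tc <- simulate_scatter(phantom$tc, phantom$mu_map,
                             study$tc_window$center_kev, study$tc_window,
                             geom, coll, mc(seed + 1L))$scatter$counts
    e_tc <- a_tc + s_tc
  }
  if (need_tl) {
    a_tl <- forward_project(phantom$tl, phantom$mu_map, geom, coll,
                            energy_kev = study$tl_window$center_kev)$counts
    s_tl <- simulate_scatter(phantom$tl, phantom$mu_map,
                             study$tl_window$center_kev, study$tl_window,
                             geom, coll, mc(seed + 2L))$scatter$counts
    e_tl_pure <- a_tl + s_tl
  }
  if (need_dual) {
    s_ds <- simulate_downscatter(phantom$tc, phantom$mu_map, study$tl_window,
                                 geom, coll, mc(seed + 3L))$counts
    e_tl_dual <- e_tl_pure + s_ds
  }

  noisy <- function(expect, target, s, window) {
    tot <- sum(expect)
    scale <- if (tot > 0) target / tot else 1  # dead window: zero counts
    counts <- with_seed(s, array(stats::rpois(length(expect),
                                              pmax(expect, 0) * scale),
                                 dim(expect)))
    projection_set(counts, geom, window,
                   meta = list(scale = scale, target = target, seed = s))
  }
  out <- list(expected = list(tc = e_tc, tl_dual = e_tl_dual,
                              tl_pure = e_tl_pure, downscatter = s_ds),
              seed = seed)
  if (need_tc)
    out$tc <- noisy(e_tc, study$targets[["tc"]], seed + 11L, study$tc_window)
  if (need_dual)
    out$tl_dual <- noisy(e_tl_dual, study$targets[["tl_dual"]], seed + 12L,
                         study$tl_window)
  if ("tl_pure" %in% components)
    out$tl_pure <- noisy(e_tl_pure, study$targets[["tl_pure"]], seed + 13L,
                         study$tl_window)
  out
}

#' Add Poisson counting noise at a target count level
#'
#' Scales the expected projections so their total equals
#' `target_total_counts` and draws independent Poisson counts per bin.
#'
#' @param projections A [projection_set()] or 3-D array of non-negative
#'   expectations.
#' @param target_total_counts Desired expected total counts (> 0).
#' @param seed Integer seed for reproducibility.
#' @return Same type as the input, with noisy counts (and scale/seed in
#'   `meta` for projection sets).
#' @export
add_poisson_noise <- function(projections, target_total_counts, seed = 1L) {
  arr <- as_projection_array(projections)
  stopifnot(target_total_counts > 0)
  if (any(arr < 0)) stop("expected projections must be non-negative")
  tot <- sum(arr)
  if (tot <= 0) stop("cannot scale all-zero projections to a positive target")
  scale <- target_total_counts / tot
  noisy <- with_seed(seed, array(stats::rpois(length(arr), arr * scale),
                                 dim(arr)))
  if (inherits(projections, "projection_set")) {
    projection_set(noisy, projections$geometry, projections$window,
                   meta = utils::modifyList(projections$meta,
                                            list(scale = scale, seed = seed)))
  } else noisy
}

#' Collapse projections onto a coarser detector grid
#'
#' Sums `factor` x `factor` bins; total counts are preserved exactly and the
#' pixel size is multiplied by `factor` (e.g. 128x128 at 3.3 mm to 64x64 at
#' 6.6 mm with factor 2).
#'
#' @param projections A [projection_set()] or 3-D array.
#' @param factor Integer collapse factor dividing both detector dimensions.
#' @return Same type as the input.
#' @export
collapse_projections <- function(projections, factor) {
  arr <- as_projection_array(projections)
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  d <- dim(arr)
  if (factor == 1L) return(projections)
  if (any(d[1:2] %% factor != 0))
    stop("factor ", factor, " does not divide the detector grid")
  nu <- d[1] %/% factor; nv <- d[2] %/% factor
  dim(arr) <- c(factor, nu, factor, nv, d[3])
  out <- apply(arr, c(2, 4, 5), sum)
  if (inherits(projections, "projection_set")) {
    g <- projections$geometry
    g2 <- spect_geometry(g$n_views, radius_mm = g$radius_mm,
                         det_pixels = c(nu, nv),
                         pixel_mm = g$pixel_mm * factor,
                         angles_deg = g$angles_deg)
    projection_set(out, g2, projections$window, projections$meta)
  } else out
}
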