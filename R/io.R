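#' Readers, writers and the end-to-end pipeline
#'
#' Volumes and attenuation maps travel as NIfTI (float32, voxel size in the
#' header); projection sets as a NIfTI 3-D stack (bin-u, bin-v, view) with a
#' JSON sidecar holding the acquisition geometry and window; phantom/study
#' specifications as YAML. Every artifact carries enough sidecar metadata to
#' re-run its producing stage.
#'
#' @name io_cli
NULL

#' Write a volume to NIfTI
#'
#' @param volume A [spect_volume()] or 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel size when `volume` is a plain array.
#' @param datatype NIfTI storage type, default `"float"` (float32).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_mm = NULL, datatype = "float") {
  arr <- as_volume_array(volume)
  if (is.null(voxel_mm)) {
    if (!inherits(volume, "spect_volume"))
      stop("voxel_mm is required for plain arrays")
    voxel_mm <- volume$voxel_mm
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path Path to a 3-D NIfTI file.
#' @return A [spect_volume()] with the voxel size from the header.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), " axes in ", path)
  pd <- RNifti::pixdim(img)
  spect_volume(array(as.numeric(img), d), voxel_mm = pd[1])
}

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a projection set (NIfTI stack + JSON sidecar)
#'
#' @param projections A [projection_set()].
#' @param path Output `.nii`/`.nii.gz` path; the sidecar replaces the
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_projections <- function(projections, path) {
  stopifnot(inherits(projections, "projection_set"))
  g <- projections$geometry
  img <- RNifti::asNifti(projections$counts)
  RNifti::pixdim(img) <- c(g$pixel_mm, g$pixel_mm, 1)
  RNifti::writeNifti(img, path, datatype = "float")
  side <- list(angles_deg = g$angles_deg,
               orbit_radius_mm = g$radius_mm,
               pixel_mm = g$pixel_mm,
               window_center_keV = if (is.null(projections$window)) NULL
                 else projections$window$center_kev,
               window_width_pct = if (is.null(projections$window)) NULL
                 else 100 * projections$window$width_frac,
               total_counts = sum(projections$counts),
               seed = projections$meta$seed,
               scale = projections$meta$scale,
               # scatter-estimate provenance, when present
               budget = projections$meta$budget,
               emission_keV = projections$meta$emission_kev,
               coarse_factor = projections$meta$coarse)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a projection set (NIfTI stack + JSON sidecar)
#'
#' @param path Path to the `.nii`/`.nii.gz` stack; the `.json` sidecar must
#'   sit next to it.
#' @return A [projection_set()].
#' @export
read_projections <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar ", sc, " for projection stack ", path)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D projection stack, got ", length(d), " axes")
  if (d[3] != length(side$angles_deg))
    stop("stack has ", d[3], " views but sidecar lists ",
         length(side$angles_deg), " angles")
  g <- spect_geometry(n_views = d[3], radius_mm = side$orbit_radius_mm,
                      det_pixels = d[1:2], pixel_mm = side$pixel_mm,
                      angles_deg = side$angles_deg)
  w <- if (!is.null(side$window_center_keV))
    energy_window(side$window_center_keV, side$window_width_pct / 100)
  projection_set(array(as.numeric(img), d), g, w,
                 meta = list(seed = side$seed, scale = side$scale,
                             total_counts = side$total_counts))
}

# tiny FNV-1a hash of a serialised R object, for run manifests
.param_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- bitwAnd(bitwXor(h, b) * 16777619, 4294967295) %% 2^32
  sprintf("%08x", h)
}

#' Run the full phantom-to-analysis pipeline
#'
#' Builds the phantom, simulates the dual-isotope study, runs the three-step
#' dual reconstruction plus the pure Tl-201 reconstruction, analyses the
#' contrasts, writes every artifact (NIfTI volumes, projection stacks with
#' sidecars, contrast tables) under `out_dir` and emits a JSON manifest with
#' inputs, seeds, parameter hashes and wall times.
#'
#' @param config List (or path to a YAML file) with optional blocks
#'   `phantom` (arguments of [cardiac_phantom_spec()]), `study`
#'   ([study_spec()] arguments), `tc_recon`/`tl_recon` ([recon_config()]
#'   arguments), `ds_photons`, and `seed`.
#' @param out_dir Output directory (created if missing).
#' @param dry_run If `TRUE`, print the stage plan and return it without
#'   computing.
#' @return List of artifact paths plus the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = "dualspect-run",
                         dry_run = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  stages <- c("phantom: build stylised cardiac torso",
              "simulate: dual-isotope + pure Tl-201 projections",
              "reconstruct: Tc-99m, down-scatter, Tl-201 (dual and pure)",
              "analyse: defect and LV contrasts",
              "write: volumes, projections, contrasts, manifest")
  if (dry_run) {
    cat("dualspect pipeline plan:\n", paste0("  - ", stages, "\n"), sep = "")
    return(invisible(list(stages = stages)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  spec <- do.call(cardiac_phantom_spec, config$phantom %||% list())
  phan <- build_cardiac_phantom(spec)
  study <- do.call(study_spec, config$study %||% list())
  timing <- c(build = as.numeric(Sys.time() - t0, units = "secs"))

  t1 <- Sys.time()
  sim <- simulate_study(phan, study, seed = seed)
  timing["simulate"] <- as.numeric(Sys.time() - t1, units = "secs")

  t2 <- Sys.time()
  tc_cfg <- do.call(recon_config,
                    utils::modifyList(list(seed = seed + 100L),
                                      config$tc_recon %||% list()))
  tl_cfg <- do.call(recon_config,
                    utils::modifyList(list(seed = seed + 200L),
                                      config$tl_recon %||% list()))
  dual <- reconstruct_dual(sim$tc, sim$tl_dual, phan$mu_map, study$geometry,
                           study$collimator, tc_cfg, tl_cfg,
                           ds_mc = mc_config(photons = config$ds_photons %||% 1e6,
                                             seed = seed + 300L))
  pure <- osem(sim$tl_pure, phan$mu_map, study$geometry, study$collimator,
               tl_cfg)
  timing["reconstruct"] <- as.numeric(Sys.time() - t2, units = "secs")

  ct_tc <- contrast_analysis(dual$tc, phan)
  ct_tl <- contrast_analysis(dual$tl, phan)
  ct_pure <- contrast_analysis(pure$volume, phan)

  paths <- list(
    tc_proj = file.path(out_dir, "projections_tc.nii.gz"),
    tl_dual_proj = file.path(out_dir, "projections_tl_dual.nii.gz"),
    tl_pure_proj = file.path(out_dir, "projections_tl_pure.nii.gz"),
    tc_vol = file.path(out_dir, "recon_tc.nii.gz"),
    tl_vol = file.path(out_dir, "recon_tl.nii.gz"),
    tl_pure_vol = file.path(out_dir, "recon_tl_pure.nii.gz"),
    contrasts = file.path(out_dir, "contrasts.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_projections(sim$tc, paths$tc_proj)
  write_projections(sim$tl_dual, paths$tl_dual_proj)
  write_projections(sim$tl_pure, paths$tl_pure_proj)
  write_volume(dual$tc, paths$tc_vol)
  write_volume(dual$tl, paths$tl_vol)
  write_volume(pure$volume, paths$tl_pure_vol)
  ct <- data.frame(
    image = c("tc_dual", "tl_dual", "tl_pure"),
    contrast_myocardium_defect = c(ct_tc$contrast_myocardium_defect,
                                   ct_tl$contrast_myocardium_defect,
                                   ct_pure$contrast_myocardium_defect),
    contrast_myocardium_lv = c(ct_tc$contrast_myocardium_lv,
                               ct_tl$contrast_myocardium_lv,
                               ct_pure$contrast_myocardium_lv))
  utils::write.csv(ct, paths$contrasts, row.names = FALSE)

  manifest <- list(
    seed = seed,
    stages = stages,
    params = list(phantom = config$phantom %||% list(),
                  study = config$study %||% list(),
                  tc_recon = config$tc_recon %||% list(),
                  tl_recon = config$tl_recon %||% list()),
    param_hash = .param_hash(config),
    artifacts = lapply(paths, identity),
    wall_times_sec = as.list(timing),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, list(contrast_table = ct, manifest_data = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
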