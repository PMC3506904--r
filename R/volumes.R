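#' Emission and attenuation volumes
#'
#' Minimal containers for 3-D grids: a `spect_volume` is a non-negative
#' emission-density grid with an isotropic voxel size; an `attenuation_map`
#' carries integer material labels so its linear attenuation coefficients can
#' be rescaled to any photon energy.
#'
#' @name volumes
NULL

#' Create an emission volume
#'
#' @param data 3-D numeric array of non-negative emission densities
#'   (relative concentration per voxel).
#' @param voxel_mm Isotropic voxel size in mm.
#' @return A `spect_volume` object (fields `data`, `voxel_mm`).
#' @export
spect_volume <- function(data, voxel_mm) {
  if (length(dim(data)) != 3L)
    stop("expected a 3-D array, got ", length(dim(data)), " axes")
  stopifnot(is.numeric(voxel_mm), voxel_mm > 0)
  if (any(data < 0)) stop("emission densities must be non-negative")
  structure(list(data = data, voxel_mm = voxel_mm), class = "spect_volume")
}

#' @export
print.spect_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spect_volume> %dx%dx%d @ %.2f mm, total %.4g\n",
              d[1], d[2], d[3], x$voxel_mm, sum(x$data)))
  invisible(x)
}

#' Create a labelled attenuation map
#'
#' @param labels 3-D integer array; 0 = air (zero attenuation), values
#'   1..length(materials) index into `materials`.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param materials Character vector mapping label values to material names
#'   present in `table`.
#' @param table Material attenuation table (see [default_material_table()]).
#' @return An `attenuation_map` object.
#' @export
attenuation_map <- function(labels, voxel_mm,
                            materials = c("soft", "lung", "bone"),
                            table = default_material_table()) {
  if (length(dim(labels)) != 3L)
    stop("expected a 3-D label array, got ", length(dim(labels)), " axes")
  stopifnot(voxel_mm > 0)
  lab <- as.integer(labels)
  if (any(lab < 0L) || any(lab > length(materials)))
    stop("labels must lie in 0..", length(materials))
  structure(list(labels = array(lab, dim(labels)), voxel_mm = voxel_mm,
                 materials = materials, table = table),
            class = "attenuation_map")
}

#' @export
print.attenuation_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<attenuation_map> %dx%dx%d @ %.2f mm; materials: %s\n",
              d[1], d[2], d[3], x$voxel_mm, paste(x$materials, collapse = ", ")))
  invisible(x)
}

#' Linear attenuation coefficients of a labelled map at a photon energy
#'
#' @param map An [attenuation_map()].
#' @param energy_kev Photon energy in keV.
#' @param component Coefficient component, as in [mu_at()].
#' @return 3-D numeric array of coefficients in 1/cm (air voxels are 0).
#' @export
mu_volume <- function(map, energy_kev, component = "total") {
  stopifnot(inherits(map, "attenuation_map"))
  mu_by_label <- c(0, vapply(map$materials, function(m)
    mu_at(m, energy_kev, component, map$table), numeric(1)))
  array(mu_by_label[map$labels + 1L], dim(map$labels))
}

# coerce volume-like input to a plain array, returning voxel size if carried
as_volume_array <- function(x) {
  if (inherits(x, "spect_volume")) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a spect_volume or 3-D array")
}
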