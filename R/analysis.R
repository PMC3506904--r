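#' Contrast and profile analysis of reconstructed volumes
#'
#' Image-quality metrics for the dual-isotope studies: equal-area regions of
#' interest on the defect, the healthy myocardium and the left-ventricular
#' cavity on the short-axis slice where the defect is best visible, the
#' contrast measure (C_myocardium - C_region) / C_myocardium computed from
#' the summed ROI counts, and band profiles through projection views.
#'
#' @name analysis
NULL

#' Sum the counts inside a region of interest
#'
#' @param slice 2-D numeric matrix (an image slice or projection view).
#' @param roi Two-column matrix of (row, col) pixel indices, or a vector of
#'   linear indices.
#' @return Total counts over the ROI pixels.
#' @export
roi_counts <- function(slice, roi) {
  stopifnot(is.matrix(slice))
  if (is.matrix(roi)) {
    if (nrow(roi) == 0L) stop("empty ROI")
    if (any(roi[, 1] < 1 | roi[, 1] > nrow(slice) |
            roi[, 2] < 1 | roi[, 2] > ncol(slice)))
      stop("ROI indices outside the image")
    sum(slice[cbind(roi[, 1], roi[, 2])])
  } else {
    if (length(roi) == 0L) stop("empty ROI")
    if (any(roi < 1 | roi > length(slice)))
      stop("ROI indices outside the image")
    sum(slice[roi])
  }
}

#' Region contrast relative to the healthy myocardium
#'
#' contrast = (C_myocardium - C_region) / C_myocardium, computed from the
#' total counts of equal-area ROIs. Invariant to global intensity rescaling;
#' at most 1, and 0 when the region matches the myocardium.
#'
#' @param c_region Total counts in the region ROI (defect or LV cavity).
#' @param c_myocardium Total counts in the healthy-myocardium ROI (> 0).
#' @return Dimensionless contrast.
#' @examples
#' contrast(200, 1000)   # 0.8
#' contrast(1000, 1000)  # 0
#' @export
contrast <- function(c_region, c_myocardium) {
  if (any(c_myocardium <= 0)) stop("myocardial counts must be positive")
  (c_myocardium - c_region) / c_myocardium
}

#' Band profile through a projection view
#'
#' Mean over a band of fixed width (default 10 pixels), per position along
#' the profile direction.
#'
#' @param view 2-D matrix (one projection view, u along rows, v along
#'   columns).
#' @param orientation `"u"` (profile along rows, band across columns) or
#'   `"v"`.
#' @param center Centre index of the band (default: middle of the view).
#' @param width Band width in pixels (default 10).
#' @return Numeric vector: the band-mean profile.
#' @export
extract_profile <- function(view, orientation = c("u", "v"), center = NULL,
                            width = 10) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(view), width >= 1)
  n_across <- if (orientation == "u") ncol(view) else nrow(view)
  if (is.null(center)) center <- (n_across + 1) / 2
  half <- (width - 1) / 2
  idx <- max(1L, ceiling(center - half)):min(n_across, floor(center + half))
  if (orientation == "u") rowMeans(view[, idx, drop = FALSE])
  else colMeans(view[idx, , drop = FALSE])
}

#' Select the short-axis slice where a defect is best visible
#'
#' Deterministic rule: among slices intersecting the defect mask, pick the
#' one maximising mean(healthy-myocardium voxels) - mean(defect voxels) of
#' the image (ties broken towards the lowest index). Invariant under global
#' intensity scaling of the image.
#'
#' @param volume A [spect_volume()] or 3-D array (the image to assess).
#' @param defect_mask Logical 3-D array marking the defect voxels.
#' @param myo_mask Logical 3-D array marking the myocardium (healthy voxels
#'   are `myo_mask & !defect_mask`).
#' @return Integer slice index (third axis).
#' @export
select_defect_slice <- function(volume, defect_mask, myo_mask) {
  arr <- as_volume_array(volume)
  stopifnot(all(dim(defect_mask) == dim(arr)), all(dim(myo_mask) == dim(arr)))
  healthy <- myo_mask & !defect_mask
  slices <- which(apply(defect_mask, 3, any) & apply(healthy, 3, any))
  if (length(slices) == 0L) stop("no defect present in the mask")
  score <- vapply(slices, function(k) {
    mean(arr[, , k][healthy[, , k]]) - mean(arr[, , k][defect_mask[, , k]])
  }, numeric(1))
  slices[which.max(score)]
}

# n mask pixels on a slice closest to a target point (grid indices);
# deterministic tie-break by linear index
.nearest_mask_pixels <- function(mask_slice, target_rc, n) {
  idx <- which(mask_slice, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("ROI mask is empty on the selected slice")
  d2 <- (idx[, 1] - target_rc[1])^2 + (idx[, 2] - target_rc[2])^2
  ord <- order(d2, idx[, 1], idx[, 2])
  idx[ord[seq_len(min(n, nrow(idx)))], , drop = FALSE]
}

#' Machine-placed equal-area ROIs for cardiac contrast analysis
#'
#' Places three equal-area ROIs from the phantom's known geometry on one
#' short-axis slice: on the defect (pixels of the defect mask nearest its
#' centroid), on the healthy myocardium (pixels nearest the point
#' diametrically opposite the defect, at mid-wall) and on the LV cavity
#' (pixels nearest the cavity centre). If a mask holds fewer pixels than
#' `area`, all three ROIs are trimmed to the smallest available count so the
#' areas stay equal.
#'
#' @param phantom A `dualspect_phantom`.
#' @param slice Slice index (third axis), e.g. from [select_defect_slice()].
#' @param defect Index into `phantom$defect_masks`, or a wall name
#'   (`"anterior"`, ...).
#' @param area Requested ROI area in pixels (default 15).
#' @return List with index matrices `defect`, `myocardium`, `lv`, the
#'   `slice`, and `area` actually used.
#' @export
cardiac_rois <- function(phantom, slice, defect = 1L, area = 15L) {
  stopifnot(inherits(phantom, "dualspect_phantom"))
  dm <- .resolve_defect(phantom, defect)
  organs <- phantom$organs
  myo <- organs == .ORGAN_LEVELS[["myocardium"]]
  lv <- organs == .ORGAN_LEVELS[["ventricle"]]
  healthy <- myo
  for (m in phantom$defect_masks) healthy <- healthy & !m

  dslice <- dm[, , slice]
  if (!any(dslice)) stop("defect does not intersect slice ", slice)
  didx <- which(dslice, arr.ind = TRUE)
  dcent <- colMeans(didx)

  # LV centre on this slice (fall back to the cavity centroid of the volume)
  lslice <- lv[, , slice]
  lcent <- if (any(lslice)) colMeans(which(lslice, arr.ind = TRUE))
           else colMeans(which(lv, arr.ind = TRUE))[1:2]
  opposite <- lcent + (lcent - dcent)

  roi_d <- .nearest_mask_pixels(dslice, dcent, area)
  roi_m <- .nearest_mask_pixels(healthy[, , slice], opposite, area)
  roi_l <- .nearest_mask_pixels(lslice, lcent, area)
  n <- min(nrow(roi_d), nrow(roi_m), nrow(roi_l))
  if (n < area)
    warning("ROI area reduced to ", n, " pixels to keep equal areas")
  list(defect = roi_d[seq_len(n), , drop = FALSE],
       myocardium = roi_m[seq_len(n), , drop = FALSE],
       lv = roi_l[seq_len(n), , drop = FALSE],
       slice = slice, area = n)
}

.resolve_defect <- function(phantom, defect) {
  if (is.character(defect)) {
    walls <- vapply(phantom$defect_masks, attr, character(1), "wall")
    hit <- which(walls == defect)
    if (length(hit) == 0L)
      stop("phantom has no '", defect, "' defect")
    phantom$defect_masks[[hit[1L]]]
  } else {
    if (length(phantom$defect_masks) < defect)
      stop("phantom has no defect #", defect)
    phantom$defect_masks[[defect]]
  }
}

#' Contrast analysis of a reconstructed volume against its phantom
#'
#' Selects the slice where the defect is best visible, places equal-area
#' ROIs from the known phantom geometry and evaluates the myocardium-defect
#' and myocardium-LV contrasts from the summed ROI counts.
#'
#' @param volume A [spect_volume()] or 3-D array congruent with the phantom
#'   grid.
#' @param phantom The `dualspect_phantom` the data were simulated from.
#' @param defect Defect selector as in [cardiac_rois()].
#' @param area ROI area in pixels.
#' @param slice Optional fixed slice index (default: automatic selection).
#' @return A `contrast_result`: `c_myocardium`, `c_defect`, `c_lv` (summed
#'   counts), `contrast_myocardium_defect`, `contrast_myocardium_lv`,
#'   `slice`, `rois`.
#' @export
contrast_analysis <- function(volume, phantom, defect = 1L, area = 15L,
                              slice = NULL) {
  arr <- as_volume_array(volume)
  stopifnot(all(dim(arr) == dim(phantom$organs)))
  dm <- .resolve_defect(phantom, defect)
  myo <- phantom$organs == .ORGAN_LEVELS[["myocardium"]]
  if (is.null(slice)) slice <- select_defect_slice(arr, dm, myo)
  rois <- cardiac_rois(phantom, slice, defect, area)
  sl <- arr[, , slice]
  c_myo <- roi_counts(sl, rois$myocardium)
  c_def <- roi_counts(sl, rois$defect)
  c_lv <- roi_counts(sl, rois$lv)
  structure(list(c_myocardium = c_myo, c_defect = c_def, c_lv = c_lv,
                 contrast_myocardium_defect = contrast(c_def, c_myo),
                 contrast_myocardium_lv = contrast(c_lv, c_myo),
                 slice = slice, rois = rois),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(paste0("<contrast_result> slice %d: myocardium-defect %.3f, ",
                     "myocardium-LV %.3f\n"),
              x$slice, x$contrast_myocardium_defect, x$contrast_myocardium_lv))
  invisible(x)
}
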