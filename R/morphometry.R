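#' Local thickness map by the largest-inscribed-sphere definition
#'
#' The thickness at a material voxel is the diameter of the largest
#' sphere that fits entirely inside the mask and contains the voxel
#' (the standard definition of trabecular thickness in bone
#' morphometry, computed via the Euclidean distance transform over
#' candidate sphere centers).  The inscribed-sphere radius at a center
#' is its distance to the phase boundary (distance to the nearest
#' background voxel center minus half a voxel), so a single isolated
#' voxel has thickness of one voxel spacing.
#'
#' Spacing must be isotropic; radii are computed in voxel units and
#' scaled once to micrometres.
#'
#' @param mask 3D logical array (nonempty, with at least one background
#'   voxel).
#' @param spacing_um Isotropic voxel spacing in micrometres.
#' @return A `thickness_map`: list with `thickness_um` (3D array,
#'   positive on the mask support, `NA` elsewhere) and `spacing_um`.
#' @export
local_thickness <- function(mask, spacing_um) {
  check_mask3d(mask)
  check_spacing(spacing_um)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("empty mask: thickness is undefined", call. = FALSE)
  if (all(mask))
    stop("mask has no background: inscribed spheres are unbounded",
         call. = FALSE)
  th <- local_thickness_cpp(mask, dim(mask))
  th <- array(th * spacing_um, dim = dim(mask))
  structure(list(thickness_um = th, spacing_um = spacing_um),
            class = "thickness_map")
}

#' Local separation (thickness of the void phase within an ROI)
#'
#' The trabecular-separation convention: [local_thickness()] applied to
#' the void phase `roi_mask & !mask`.
#'
#' @param mask 3D logical array of the material phase.
#' @param roi_mask 3D logical array containing `mask`.
#' @param spacing_um Isotropic voxel spacing in micrometres.
#' @return A `thickness_map` over the void phase.
#' @export
separation <- function(mask, roi_mask, spacing_um) {
  check_mask3d(mask)
  check_mask3d(roi_mask)
  if (!identical(dim(mask), dim(roi_mask)))
    stop("mask and roi_mask must have the same shape", call. = FALSE)
  if (any(mask & !roi_mask))
    stop("roi_mask must contain mask", call. = FALSE)
  void <- roi_mask & !mask
  if (!any(void)) stop("void phase is empty within the ROI", call. = FALSE)
  local_thickness(void, spacing_um)
}

#' Summary statistics of a thickness map
#' @param object A `thickness_map`.
#' @param ... Unused.
#' @return List with `min`, `max`, `mean` (um) over defined voxels.
#' @export
summary.thickness_map <- function(object, ...) {
  v <- object$thickness_um[!is.na(object$thickness_um)]
  list(min = min(v), max = max(v), mean = mean(v))
}

#' Tissue-level morphometry report
#'
#' Computes, for one label of a segmented volume: the exact volume
#' (voxel count times spacing cubed), the axis-aligned bounding extents
#' in the anatomical frame (the width/depth/height of the tissue),
#' local-thickness statistics, the global degree of anisotropy (the
#' anisotropy index of a fabric tensor fitted to the whole label mask),
#' and -- when an ROI is given -- separation statistics and the volume
#' fraction within the ROI.
#'
#' @param x A [label_map()], or a 3D integer/logical array.
#' @param label Label value to analyze (ignored for a logical array).
#' @param spacing_um Voxel spacing (taken from `x` when it is a
#'   `label_map`).
#' @param axis_map Axis mapping (likewise).
#' @param roi Optional 3D logical ROI mask for separation and volume
#'   fraction.
#' @param directions Direction set for the global fabric fit.
#' @param line_spacing_vox Test-line spacing for the global fabric fit.
#' @param thickness Set `FALSE` to skip the (relatively costly) local
#'   thickness statistics.
#' @return A `morphometry_report` list: `label`, `volume_mm3`,
#'   `extent_mm` (named X/Y/Z), `thickness_um` (min/max/mean),
#'   `global_anisotropy`, `global_fabric` (the fitted tensor), and with
#'   an ROI `separation_um` and `volume_fraction`.
#' @export
tissue_metrics <- function(x, label = NULL, spacing_um = NULL,
                           axis_map = NULL, roi = NULL,
                           directions = sample_directions(128),
                           line_spacing_vox = 2, thickness = TRUE) {
  if (inherits(x, "label_map")) {
    spacing_um <- spacing_um %||% x$spacing_um
    axis_map <- axis_map %||% x$axis_map
    grid <- x$labels
  } else {
    grid <- x
  }
  axis_map <- axis_map %||% c("X", "Y", "Z")
  check_mask3d(grid)
  check_spacing(spacing_um)
  check_axis_map(axis_map)
  if (is.logical(grid)) {
    mask <- grid
    label <- label %||% TRUE
  } else {
    if (is.null(label)) stop("label must be given", call. = FALSE)
    mask <- grid == label
  }
  if (!any(mask))
    stop("label ", label, " is absent from the volume", call. = FALSE)

  n_mat <- sum(mask)
  volume_mm3 <- n_mat * spacing_um^3 / 1e9

  idx <- which(mask, arr.ind = TRUE)
  ext_vox <- apply(idx, 2, function(v) diff(range(v)) + 1L)
  perm <- anat_perm(axis_map)
  extent_mm <- setNames(ext_vox[perm] * spacing_um / 1000, .anat_axes)

  th_stats <- NULL
  if (isTRUE(thickness)) {
    th_stats <- summary.thickness_map(local_thickness(mask, spacing_um))
  }

  # direction components are anatomical; express in the array frame
  dirs_array <- directions
  dirs_array[, ] <- unclass(directions)[, match(axis_map, .anat_axes)]
  prof <- compute_mil(mask, spacing_um, dirs_array, line_spacing_vox)
  fab <- fit_fabric_tensor(prof)
  # report the fabric in the anatomical frame
  vec <- fab$eigenvectors[perm, , drop = FALSE]
  for (i in 1:3) vec[, i] <- canonicalize_axial(vec[, i])
  fab$eigenvectors <- vec

  rep <- list(label = label, voxel_count = n_mat, volume_mm3 = volume_mm3,
              extent_mm = extent_mm, thickness_um = th_stats,
              global_anisotropy = anisotropy_index(fab),
              global_fabric = fab)
  if (!is.null(roi)) {
    sep <- separation(mask, roi, spacing_um)
    rep$separation_um <- summary.thickness_map(sep)
    rep$volume_fraction <- n_mat / sum(roi)
  }
  structure(rep, class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("<morphometry_report> label", format(x$label),
      sprintf("| volume %.4g mm^3 | extents %s mm | DA %.3f\n",
              x$volume_mm3,
              paste(sprintf("%s=%.3g", names(x$extent_mm), x$extent_mm),
                    collapse = " "),
              x$global_anisotropy))
  if (!is.null(x$thickness_um))
    cat(sprintf("  thickness um: min %.3g max %.3g mean %.3g\n",
                x$thickness_um$min, x$thickness_um$max, x$thickness_um$mean))
  if (!is.null(x$separation_um))
    cat(sprintf("  separation um: min %.3g max %.3g mean %.3g | BV/TV %.3f\n",
                x$separation_um$min, x$separation_um$max,
                x$separation_um$mean, x$volume_fraction))
  invisible(x)
}
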