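#' Directional Mean Intercept Length profile of a binary volume
#'
#' For each direction a family of parallel test lines (perpendicular
#' spacing `line_spacing_vox` voxels) is traced through the bounding box
#' of the material phase.  Samples are taken every half voxel along each
#' line with nearest-voxel lookup; an intercept is a maximal run of
#' consecutive material samples.  The Mean Intercept Length along a
#' direction is the total sampled material length divided by the number
#' of intercepts.  Runs truncated by the volume boundary count as one
#' intercept, which only matters in the solid-volume limit.
#'
#' Long MIL along a direction means structures are elongated that way:
#' fiber bundles give long intercepts along the bundle axis and short
#' chords across it.
#'
#' @param mask 3D logical (or 0/1) array; `TRUE` is material.
#' @param spacing_um Isotropic voxel spacing in micrometres.
#' @param directions A [sample_directions()] set (unit row vectors).
#' @param line_spacing_vox Perpendicular spacing of the test lines in
#'   voxels (>= 1; default 2).
#' @return A `mil_profile` data frame with one row per direction:
#'   `dx, dy, dz, intercept_count, total_material_length_um, mil_um`
#'   (`mil_um` is `NA` where `intercept_count` is zero).  An all-void
#'   mask yields zero counts for every direction.
#' @seealso [fit_fabric_tensor()]
#' @export
compute_mil <- function(mask, spacing_um, directions,
                        line_spacing_vox = 2) {
  check_mask3d(mask)
  check_spacing(spacing_um)
  if (!inherits(directions, "direction_set"))
    stop("directions must be a direction_set from sample_directions()",
         call. = FALSE)
  if (!is.numeric(line_spacing_vox) || length(line_spacing_vox) != 1L ||
      line_spacing_vox < 1)
    stop("line_spacing_vox must be >= 1", call. = FALSE)

  storage.mode(mask) <- "logical"
  res <- mil_trace_cpp(mask, dim(mask), unclass(directions),
                       as.numeric(line_spacing_vox))
  count <- res$intercept_count
  total_um <- res$material_samples * 0.5 * spacing_um
  out <- data.frame(dx = directions[, 1], dy = directions[, 2],
                    dz = directions[, 3],
                    intercept_count = count,
                    total_material_length_um = total_um,
                    mil_um = ifelse(count > 0, total_um / count, NA_real_))
  attr(out, "spacing_um") <- spacing_um
  attr(out, "line_spacing_vox") <- line_spacing_vox
  class(out) <- c("mil_profile", "data.frame")
  out
}
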