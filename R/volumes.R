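#' Voxel volume with physical spacing and anatomical axis mapping
#'
#' A `voxel_volume` couples a 3D scalar grid with its isotropic voxel
#' spacing (micrometres) and an `axis_map` that assigns each array
#' dimension to an anatomical axis: X (lateral-medial), Y
#' (ventral-dorsal), Z (cranial-caudal).  Storage order carries no
#' anatomical meaning; only `axis_map` does.  Voxel coordinates are
#' 0-based voxel centers, so physical coordinate = index x spacing_um.
#'
#' @param data 3D numeric, integer, or logical array.
#' @param spacing_um Isotropic voxel spacing in micrometres (> 0).
#' @param axis_map Character permutation of `c("X", "Y", "Z")`;
#'   `axis_map[i]` is the anatomical axis of array dimension `i`.
#' @return An object of class `voxel_volume` with elements `data`,
#'   `spacing_um`, `axis_map`.
#' @export
voxel_volume <- function(data, spacing_um, axis_map = c("X", "Y", "Z")) {
  check_mask3d(data)
  check_spacing(spacing_um)
  check_axis_map(axis_map)
  structure(list(data = data, spacing_um = spacing_um, axis_map = axis_map),
            class = "voxel_volume")
}

#' Integer label map over a voxel grid
#'
#' Like [voxel_volume()] but for segmented volumes: a non-negative
#' integer grid plus a legend naming each tissue class.  Label 0 is
#' background and need not appear in the legend.
#'
#' @param labels 3D array of non-negative integers.
#' @param legend Named character vector mapping label values (names) to
#'   tissue names, e.g. `c("1" = "bone", "2" = "disc")`.  Every nonzero
#'   label present in the grid must appear.
#' @param spacing_um,axis_map See [voxel_volume()].
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, legend, spacing_um,
                      axis_map = c("X", "Y", "Z")) {
  check_mask3d(labels)
  check_spacing(spacing_um)
  check_axis_map(axis_map)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers", call. = FALSE)
  present <- setdiff(sort(unique(as.vector(labels))), 0)
  if (!all(as.character(present) %in% names(legend)))
    stop("legend is missing labels present in the grid: ",
         paste(setdiff(as.character(present), names(legend)),
               collapse = ", "), call. = FALSE)
  structure(list(labels = labels, legend = legend, spacing_um = spacing_um,
                 axis_map = axis_map),
            class = "label_map")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", x$spacing_um, " um, axes [",
      paste(x$axis_map, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$labels), collapse = " x "),
      " voxels, spacing ", x$spacing_um, " um, labels: ",
      paste(sprintf("%s=%s", names(x$legend), x$legend), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
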