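#' Sliding-window specification
#'
#' @param edge_vox Cubic window edge in voxels.
#' @param stride_vox Stride between window origins in voxels; must not
#'   exceed `edge_vox` so the tiling has no gaps.  The defaults (edge 32,
#'   stride 16) give 50% overlap; at a 6.48 um voxel they correspond to
#'   ~0.2 mm windows, the scale at which fiber bundles in dense
#'   fibrocartilage appear locally parallel.
#' @param min_material_fraction Windows with a lower material fraction
#'   are skipped.
#' @return A `window_spec` list.
#' @export
window_spec <- function(edge_vox = 32L, stride_vox = 16L,
                        min_material_fraction = 0.05) {
  if (!is.numeric(edge_vox) || edge_vox < 1 || edge_vox != round(edge_vox))
    stop("edge_vox must be a positive integer", call. = FALSE)
  if (!is.numeric(stride_vox) || stride_vox < 1 ||
      stride_vox != round(stride_vox))
    stop("stride_vox must be a positive integer", call. = FALSE)
  if (stride_vox > edge_vox)
    stop("stride_vox must be <= edge_vox (gap-free tiling)", call. = FALSE)
  if (!is.numeric(min_material_fraction) || min_material_fraction < 0 ||
      min_material_fraction >= 1)
    stop("min_material_fraction must lie in [0, 1)", call. = FALSE)
  structure(list(edge_vox = as.integer(edge_vox),
                 stride_vox = as.integer(stride_vox),
                 min_material_fraction = min_material_fraction),
            class = "window_spec")
}

.field_columns <- c("cx_um", "cy_um", "cz_um",
                    "e1x", "e1y", "e1z", "e2x", "e2y", "e2z",
                    "e3x", "e3y", "e3z",
                    "l1_um", "l2_um", "l3_um",
                    "magnitude_um", "anisotropy_index", "material_fraction")

.empty_field_samples <- function() {
  cols <- c(.field_columns, "i0", "j0", "k0")
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  df
}

#' Map an orientation vector field over a masked volume
#'
#' Tiles the volume with cubic sliding windows, computes a directional
#' MIL profile and fabric tensor in each, and keeps one sample per
#' window that passes the material-fraction threshold and yields a
#' non-degenerate fit: the window center (um, anatomical frame), the
#' primary eigenvector (canonical axial representative), the magnitude
#' (primary eigenvalue, um), the 0-1 anisotropy index, and the material
#' fraction.  Windows that fail are skipped and counted, never patched.
#' A window's sample is attributed to its geometric center.
#'
#' Samples are ordered by window grid index: anatomical Z slowest, then
#' Y, then X.
#'
#' @param mask 3D logical array (material = `TRUE`), a `voxel_volume`,
#'   or a `phantom_volume`.
#' @param spacing_um,axis_map Voxel spacing and axis mapping; taken from
#'   the object when `mask` is a volume class.
#' @param window A [window_spec()].
#' @param directions A [sample_directions()] set; components are read in
#'   the anatomical X/Y/Z frame and mapped into array order internally.
#' @param line_spacing_vox Test-line spacing for [compute_mil()].
#' @return An `orientation_field`: a data frame of samples (one row per
#'   retained window) with attributes `window`, `source_shape`,
#'   `spacing_um`, `axis_map`, and `counts` (tiled, retained,
#'   skipped_low_fraction, skipped_fit).  Zero retained windows give an
#'   empty field, not an error.
#' @export
map_orientation_field <- function(mask, spacing_um = NULL, axis_map = NULL,
                                  window = window_spec(),
                                  directions = sample_directions(128),
                                  line_spacing_vox = 2) {
  if (inherits(mask, "phantom_volume")) {
    spacing_um <- spacing_um %||% mask$spacing_um
    axis_map <- axis_map %||% mask$axis_map
    mask <- mask$mask
  } else if (inherits(mask, "voxel_volume")) {
    spacing_um <- spacing_um %||% mask$spacing_um
    axis_map <- axis_map %||% mask$axis_map
    mask <- mask$data != 0
  }
  axis_map <- axis_map %||% c("X", "Y", "Z")
  check_mask3d(mask)
  check_spacing(spacing_um)
  check_axis_map(axis_map)
  if (!inherits(window, "window_spec"))
    stop("window must be a window_spec", call. = FALSE)
  dims <- dim(mask)
  edge <- window$edge_vox
  if (any(dims < edge))
    stop("window edge (", edge, ") exceeds volume shape (",
         paste(dims, collapse = "x"), ")", call. = FALSE)
  storage.mode(mask) <- "logical"

  starts <- lapply(dims, function(n) seq(1L, n - edge + 1L, by = window$stride_vox))
  perm <- anat_perm(axis_map)   # array dim of X, Y, Z
  # direction components are anatomical (X, Y, Z); express them in the
  # array frame so a permuted volume + axis_map yields the same
  # anatomical-frame field
  dirs_array <- directions
  dirs_array[, ] <- unclass(directions)[, match(axis_map, .anat_axes)]
  # enumerate windows with anatomical Z slowest, Y, then X fastest
  gr <- expand.grid(x = seq_along(starts[[perm[1]]]),
                    y = seq_along(starts[[perm[2]]]),
                    z = seq_along(starts[[perm[3]]]))
  n_tiled <- nrow(gr)
  skipped_frac <- 0L
  skipped_fit <- 0L
  rows <- vector("list", n_tiled)
  nkeep <- 0L
  minvox <- window$min_material_fraction * edge^3

  for (w in seq_len(n_tiled)) {
    s <- integer(3)
    s[perm[1]] <- starts[[perm[1]]][gr$x[w]]
    s[perm[2]] <- starts[[perm[2]]][gr$y[w]]
    s[perm[3]] <- starts[[perm[3]]][gr$z[w]]
    sub <- mask[s[1]:(s[1] + edge - 1L),
                s[2]:(s[2] + edge - 1L),
                s[3]:(s[3] + edge - 1L)]
    nmat <- sum(sub)
    frac <- nmat / edge^3
    if (nmat < minvox || nmat == 0L) {
      skipped_frac <- skipped_frac + 1L
      next
    }
    ft <- tryCatch({
      prof <- compute_mil(sub, spacing_um, dirs_array, line_spacing_vox)
      fit_fabric_tensor(prof)
    }, error = function(e) NULL)
    if (is.null(ft)) {
      skipped_fit <- skipped_fit + 1L
      next
    }
    center_arr <- (s - 1) + (edge - 1) / 2          # array-frame voxel coords
    center_anat <- center_arr[perm] * spacing_um    # anatomical X, Y, Z
    ev <- ft$eigenvectors[perm, , drop = FALSE]     # components -> anatomical
    for (i in 1:3) ev[, i] <- canonicalize_axial(ev[, i])
    lam <- ft$eigenvalues_um
    nkeep <- nkeep + 1L
    rows[[nkeep]] <- c(center_anat, ev[, 1], ev[, 2], ev[, 3], lam,
                       lam[1], 1 - lam[3] / lam[1], frac, s[1], s[2], s[3])
  }

  if (nkeep == 0L) {
    samples <- .empty_field_samples()
  } else {
    samples <- as.data.frame(do.call(rbind, rows[seq_len(nkeep)]))
    names(samples) <- c(.field_columns, "i0", "j0", "k0")
  }
  structure(samples,
            window = window, source_shape = dims, spacing_um = spacing_um,
            axis_map = axis_map,
            counts = list(tiled = n_tiled, retained = nkeep,
                          skipped_low_fraction = skipped_frac,
                          skipped_fit = skipped_fit),
            class = c("orientation_field", "data.frame"))
}

#' Number of retained samples (the field's total vector count)
#' @param field An `orientation_field`.
#' @return Integer count of retained windows.
#' @export
field_size <- function(field) {
  stopifnot(inherits(field, "orientation_field"))
  nrow(field)
}

#' Primary eigenvectors of a field as a matrix
#' @param field An `orientation_field`.
#' @return `n x 3` matrix of canonical axial unit vectors (X, Y, Z).
#' @export
field_e1 <- function(field) {
  stopifnot(inherits(field, "orientation_field"))
  as.matrix(field[, c("e1x", "e1y", "e1z")])
}

#' Assign each field sample to a phantom region
#'
#' A window belongs to the majority label among its material voxels
#' (ties go to the smallest label).  Windows whose material voxels carry
#' no nonzero label get `NA`.
#'
#' @param field An `orientation_field`.
#' @param labels 3D integer array of region labels (same grid as the
#'   mask the field was computed from), or a `phantom_volume` with
#'   labels.
#' @param mask The binary mask the field was computed from (taken from
#'   the phantom when `labels` is a `phantom_volume`).
#' @return Integer vector of region labels, one per field sample.
#' @export
window_region_labels <- function(field, labels, mask = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  if (inherits(labels, "phantom_volume")) {
    mask <- mask %||% labels$mask
    labels <- labels$labels
  }
  if (is.null(labels)) stop("no labels available", call. = FALSE)
  edge <- attr(field, "window")$edge_vox
  n <- nrow(field)
  out <- rep(NA_integer_, n)
  for (w in seq_len(n)) {
    i0 <- field$i0[w]; j0 <- field$j0[w]; k0 <- field$k0[w]
    sub_l <- labels[i0:(i0 + edge - 1L), j0:(j0 + edge - 1L),
                    k0:(k0 + edge - 1L)]
    sub_m <- mask[i0:(i0 + edge - 1L), j0:(j0 + edge - 1L),
                  k0:(k0 + edge - 1L)]
    lab <- sub_l[sub_m & sub_l > 0]
    if (length(lab) == 0) next
    tab <- tabulate(lab)
    out[w] <- which.max(tab)   # first max = smallest label on ties
  }
  out
}

#' @export
print.orientation_field <- function(x, ...) {
  ct <- attr(x, "counts")
  cat("<orientation_field> ", nrow(x), " samples (of ", ct$tiled,
      " windows; ", ct$skipped_low_fraction, " low-fraction, ",
      ct$skipped_fit, " degenerate skips), edge ",
      attr(x, "window")$edge_vox, " vox, spacing ",
      attr(x, "spacing_um"), " um\n", sep = "")
  invisible(x)
}
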