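# TIFF stack readers/writers and the CSV field export.
#
# Storage contract: slices are stored along array dimension 1; all
# anatomical semantics live in axis_map.  Integer data (masks, labels)
# are stored losslessly at 8 or 16 bits.  Float data are stored as
# 32-bit fixed point scaled to [0, 1] with the scale recorded in the
# JSON sidecar (about 1e-9 relative precision, i.e. float32-level
# fidelity).

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write a voxel volume as a multi-page TIFF stack
#'
#' Slices (array dimension 1) become TIFF pages.  Integer-valued data
#' round-trip bit for bit (8-bit for values up to 255 -- binary masks
#' are stored with values exactly 0/1 -- 16-bit up to 65535); other
#' numeric data are stored as scaled 32-bit fixed point.  A JSON
#' sidecar `<path>.json` records spacing, axis map, encoding, scale,
#' and (for label maps) the legend, so [read_volume_stack()] can
#' restore the object without repeating the metadata.
#'
#' @param volume A [voxel_volume()], [label_map()], `phantom_volume`,
#'   or bare 3D array (then `spacing_um` is required).
#' @param path Output file path (parent directory must exist).
#' @param spacing_um,axis_map Metadata when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume_stack <- function(volume, path, spacing_um = NULL,
                               axis_map = NULL) {
  legend <- NULL
  if (inherits(volume, "voxel_volume")) {
    data <- volume$data; spacing_um <- volume$spacing_um
    axis_map <- volume$axis_map
  } else if (inherits(volume, "label_map")) {
    data <- volume$labels; spacing_um <- volume$spacing_um
    axis_map <- volume$axis_map; legend <- volume$legend
  } else if (inherits(volume, "phantom_volume")) {
    data <- volume$mask; spacing_um <- volume$spacing_um
    axis_map <- volume$axis_map
  } else {
    data <- volume
  }
  check_mask3d(data)
  axis_map <- axis_map %||% c("X", "Y", "Z")
  check_spacing(spacing_um)
  check_axis_map(axis_map)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)

  if (is.logical(data)) storage.mode(data) <- "integer"
  vals <- as.vector(data)
  integerish <- is.integer(data) ||
    (all(is.finite(vals)) && all(vals == round(vals)) &&
       min(vals) >= 0 && max(vals) <= 65535)
  if (integerish) {
    bits <- if (max(vals) <= 255) 8L else 16L
    scale <- 2^bits - 1
    encoding <- paste0("uint", bits)
  } else {
    if (any(!is.finite(vals)))
      stop("cannot store non-finite values; replace NA/Inf first",
           call. = FALSE)
    bits <- 32L
    lo <- min(vals)
    scale <- max(vals) - lo
    if (scale == 0) scale <- 1
    encoding <- "fixed32"
  }
  pages <- lapply(seq_len(dim(data)[1]), function(s) {
    m <- data[s, , ]
    if (encoding == "fixed32") (m - lo) / scale else m / scale
  })
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e)
                   stop("cannot write TIFF stack to ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  meta <- list(spacing_um = spacing_um, axis_map = axis_map,
               encoding = encoding, shape = dim(data))
  if (encoding == "fixed32") {
    meta$offset <- lo
    meta$scale <- scale
  }
  if (!is.null(legend)) meta$legend <- as.list(legend)
  .write_sidecar(path, meta)
  invisible(path)
}

#' Read a voxel volume from a TIFF stack
#'
#' Accepts a multi-page TIFF or a directory of single-slice TIFFs in
#' lexicographic order; slices are stacked along array dimension 1.
#' Metadata come from the JSON sidecar written by
#' [write_volume_stack()] when present, otherwise `spacing_um` must be
#' given explicitly -- spacing is never guessed.  Integer data with a
#' legend yield a [label_map()], otherwise a [voxel_volume()].
#'
#' @param path TIFF file or slice directory.
#' @param spacing_um Voxel spacing; required when no sidecar exists.
#' @param axis_map Axis mapping (default from sidecar, else X, Y, Z).
#' @param legend Optional label legend; turns an integer volume into a
#'   [label_map()].
#' @return A [voxel_volume()] or [label_map()].
#' @export
read_volume_stack <- function(path, spacing_um = NULL, axis_map = NULL,
                              legend = NULL) {
  meta <- NULL
  if (file.exists(.sidecar_path(path)))
    meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  spacing_um <- spacing_um %||% meta$spacing_um
  if (is.null(spacing_um))
    stop("spacing_um is required (no sidecar found); spacing is never guessed",
         call. = FALSE)
  axis_map <- axis_map %||% (meta$axis_map %||% c("X", "Y", "Z"))
  if (is.null(legend) && !is.null(meta$legend))
    legend <- unlist(meta$legend)
  encoding <- meta$encoding %||% "uint"

  read_one <- function(f, as_is) {
    r <- tiff::readTIFF(f, all = TRUE, as.is = as_is)
    if (!is.list(r)) r <- list(r)
    r
  }
  as_is <- encoding != "fixed32"
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0)
      stop("no TIFF slices found in ", path, call. = FALSE)
    pages <- unlist(lapply(files, read_one, as_is = as_is),
                    recursive = FALSE)
  } else if (file.exists(path)) {
    pages <- read_one(path, as_is)
  } else {
    stop("no such file or directory: ", path, call. = FALSE)
  }
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent slice shapes across the stack", call. = FALSE)
  arr <- array(0, dim = c(length(pages), shapes[1, 1], shapes[2, 1]))
  for (s in seq_along(pages)) arr[s, , ] <- pages[[s]]
  if (encoding == "fixed32") {
    arr <- arr * meta$scale + meta$offset
  } else if (as_is) {
    storage.mode(arr) <- "integer"
  }
  if (!is.null(legend) && is.integer(arr)) {
    label_map(arr, legend, spacing_um, axis_map)
  } else {
    voxel_volume(arr, spacing_um, axis_map)
  }
}

#' Export an orientation field as CSV
#'
#' One row per retained window, ordered by window grid index
#' (anatomical Z-major, then Y, then X -- the field's native order).
#' Header (exact):
#' `cx_um,cy_um,cz_um,e1x,e1y,e1z,e2x,e2y,e2z,e3x,e3y,e3z,l1_um,l2_um,l3_um,magnitude_um,anisotropy_index,material_fraction`.
#' Floats are serialized with 9 significant digits; comma separator,
#' UNIX newlines, no quoting, `.` decimal.  An empty field writes the
#' header only.
#'
#' @param field An `orientation_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_field_csv <- function(field, path) {
  stopifnot(inherits(field, "orientation_field"))
  header <- paste(.field_columns, collapse = ",")
  lines <- header
  if (nrow(field) > 0) {
    cells <- vapply(.field_columns, function(cn)
      formatC(field[[cn]], digits = 9, format = "g"), character(nrow(field)))
    if (nrow(field) == 1) cells <- matrix(cells, nrow = 1)
    lines <- c(header, apply(cells, 1, paste, collapse = ","))
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    stop("cannot write CSV to ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read back an exported orientation-field CSV
#' @param path CSV written by [export_field_csv()].
#' @return A data frame with the exported columns.
#' @export
read_field_csv <- function(path) {
  read.csv(path, header = TRUE, colClasses = "numeric")
}

#' Write a plane histogram as CSV
#'
#' Columns: `bin_start_deg`, `bin_end_deg`, `count`,
#' `sum_magnitude_um`; the excluded (out-of-plane) sample count is kept
#' in the companion JSON summaries, not dropped.
#'
#' @param hist A `plane_histogram` from [rose_histogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "plane_histogram"))
  nb <- length(hist$counts)
  lines <- c("bin_start_deg,bin_end_deg,count,sum_magnitude_um",
             vapply(seq_len(nb), function(b)
               paste(formatC(hist$bin_edges_deg[b], digits = 9, format = "g"),
                     formatC(hist$bin_edges_deg[b + 1], digits = 9,
                             format = "g"),
                     hist$counts[b],
                     formatC(hist$sum_magnitude_um[b], digits = 9,
                             format = "g"), sep = ","),
               character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
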