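# Reductions of an orientation field into axial directional statistics:
# dominant-axis fractions, anatomical-plane rose histograms (frequency
# and sum-magnitude weightings), anisotropy summaries, and regional
# contrasts.  All statistics treat orientations as axial (v == -v) and
# weight each retained window as one vector.

.planes <- c("sagittal_YZ", "frontal_XZ", "transverse_XY")
# in-plane component pair per plane: angle measured from the first
# toward the second, folded to [0, 180)
.plane_axes <- list(sagittal_YZ = c("Y", "Z"),
                    frontal_XZ = c("X", "Z"),
                    transverse_XY = c("X", "Y"))

#' Dominant anatomical-axis fractions of an orientation field
#'
#' Each sample is assigned to the anatomical axis of its primary
#' eigenvector's largest-magnitude component (ties broken X before Y
#' before Z, matching [canonicalize_axial()]).
#'
#' @param field A nonempty `orientation_field`.
#' @return An `axis_summary`: list with per-axis `counts`, `fractions`,
#'   and `total`.
#' @export
dominant_axis_fractions <- function(field) {
  stopifnot(inherits(field, "orientation_field"))
  n <- nrow(field)
  if (n == 0) stop("empty orientation field", call. = FALSE)
  dom <- dominant_axis(field)
  counts <- vapply(.anat_axes, function(a) sum(dom == a), integer(1))
  structure(list(counts = counts, fractions = counts / n, total = n),
            class = "axis_summary")
}

#' Dominant axis of each sample
#' @param field An `orientation_field`.
#' @return Character vector (`"X"`, `"Y"`, `"Z"`), one per sample.
#' @export
dominant_axis <- function(field) {
  e1 <- abs(field_e1(field))
  if (nrow(e1) == 0) return(character(0))
  .anat_axes[apply(e1, 1, which.max)]   # which.max takes X before Y before Z
}

#' Project an axial orientation onto an anatomical plane
#'
#' Drops the out-of-plane component and returns the in-plane angle,
#' measured from the plane's first axis toward its second (sagittal:
#' from +Y toward +Z; frontal: from +X toward +Z; transverse: from +X
#' toward +Y) and folded to `[0, 180)` because orientations are axial.
#' Samples with an in-plane norm below `1e-6` are excluded
#' (`NA` angle).
#'
#' @param e1 Unit 3-vector in the anatomical frame, or an `n x 3`
#'   matrix.
#' @param plane `"sagittal_YZ"`, `"frontal_XZ"`, or `"transverse_XY"`.
#' @return A data frame with `angle_deg` in `[0, 180)` (`NA` when
#'   excluded) and `in_plane_weight` (norm of the in-plane pair).
#' @examples
#' project_to_plane(c(0, 0.6, 0.8), "sagittal_YZ") # 53.13 deg, weight 1
#' @export
project_to_plane <- function(e1, plane = .planes) {
  plane <- match.arg(plane)
  if (!is.matrix(e1)) e1 <- matrix(e1, nrow = 1)
  colnames(e1) <- NULL
  ax <- match(.plane_axes[[plane]], .anat_axes)
  c1 <- e1[, ax[1]]
  c2 <- e1[, ax[2]]
  w <- sqrt(c1^2 + c2^2)
  ang <- (atan2(c2, c1) * 180 / pi) %% 180
  ang[ang >= 180] <- 0            # guard the fold boundary
  ang[w < 1e-6] <- NA_real_
  data.frame(angle_deg = ang, in_plane_weight = w)
}

#' Rose histogram of in-plane fiber angles
#'
#' Bins the plane-projected angles of a field into `n_bins` equal-width
#' half-open bins over `[0, 180)`.  Both weightings of the field are
#' returned in one object: `counts` increments by one per sample (fiber
#' frequency, the structural geometry), `sum_magnitude_um` accumulates
#' each sample's magnitude (primary eigenvalue) as a proxy for total
#' reinforcement along that direction.  Out-of-plane samples are counted
#' in `excluded`, never silently dropped; `sum(counts) + excluded`
#' equals the field size.
#'
#' @param field A nonempty `orientation_field`.
#' @param plane See [project_to_plane()].
#' @param n_bins Number of bins (>= 4).
#' @return A `plane_histogram`: list with `plane`, `bin_edges_deg`
#'   (length `n_bins + 1`), `counts`, `sum_magnitude_um`, `excluded`,
#'   `total`.
#' @export
rose_histogram <- function(field, plane = .planes, n_bins = 18L) {
  stopifnot(inherits(field, "orientation_field"))
  plane <- match.arg(plane)
  if (nrow(field) == 0) stop("empty orientation field", call. = FALSE)
  if (!is.numeric(n_bins) || n_bins < 4 || n_bins != round(n_bins))
    stop("n_bins must be an integer >= 4", call. = FALSE)
  n_bins <- as.integer(n_bins)
  pr <- project_to_plane(field_e1(field), plane)
  edges <- seq(0, 180, length.out = n_bins + 1L)
  width <- 180 / n_bins
  ok <- !is.na(pr$angle_deg)
  bin <- pmin(floor(pr$angle_deg[ok] / width), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  mag <- field$magnitude_um[ok]
  sum_mag <- vapply(seq_len(n_bins),
                    function(b) sum(mag[bin == b]), numeric(1))
  structure(list(plane = plane, bin_edges_deg = edges, counts = counts,
                 sum_magnitude_um = sum_mag, excluded = sum(!ok),
                 total = nrow(field)),
            class = "plane_histogram")
}

.summary_of <- function(a) {
  n <- length(a)
  list(mean = mean(a), median = median(a),
       sd = if (n > 1) sd(a) else 0, n = n)
}

#' Summarize the anisotropy indices of a field
#'
#' Mean, median, sample (n-1) standard deviation, and count of the 0-1
#' anisotropy indices, overall or grouped by dominant anatomical axis.
#' A single sample has sd 0 by convention.
#'
#' @param field A nonempty `orientation_field`.
#' @param by `"none"` for one overall summary, `"axis"` for one per
#'   dominant axis.
#' @param axes With `by = "axis"`: the axes to report.  The default
#'   reports the axes that have samples; naming an axis with no samples
#'   is an error.
#' @return An `anisotropy_summary` (list with `mean`, `median`, `sd`,
#'   `n`) or, for `by = "axis"`, a named list of them.
#' @export
summarize_anisotropy <- function(field, by = c("none", "axis"),
                                 axes = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  by <- match.arg(by)
  if (nrow(field) == 0) stop("empty orientation field", call. = FALSE)
  a <- field$anisotropy_index
  if (by == "none") {
    return(structure(.summary_of(a), class = "anisotropy_summary"))
  }
  dom <- dominant_axis(field)
  if (is.null(axes)) axes <- .anat_axes[.anat_axes %in% dom]
  out <- lapply(axes, function(ax) {
    g <- a[dom == ax]
    if (length(g) == 0)
      stop("no samples in dominant-axis group '", ax, "'", call. = FALSE)
    structure(.summary_of(g), class = "anisotropy_summary")
  })
  names(out) <- axes
  out
}

#' Anisotropy contrast between two named regions
#'
#' Summarizes the anisotropy index per region and reports the
#' difference of means `mean(region_a) - mean(region_b)` -- e.g. the
#' rim-versus-center contrast of a disc.
#'
#' @param field A nonempty `orientation_field`.
#' @param regions Vector of region labels, one per sample (e.g. from
#'   [window_region_labels()]).
#' @param region_a,region_b Region labels to contrast; each must have
#'   at least one sample.
#' @return A `region_contrast`: list with per-region
#'   `anisotropy_summary` objects and `difference_of_means`.
#' @export
region_contrast <- function(field, regions, region_a, region_b) {
  stopifnot(inherits(field, "orientation_field"))
  if (length(regions) != nrow(field))
    stop("regions must have one label per field sample", call. = FALSE)
  a <- field$anisotropy_index
  pick <- function(r) {
    g <- a[!is.na(regions) & regions == r]
    if (length(g) == 0)
      stop("region '", r, "' has no samples", call. = FALSE)
    g
  }
  ga <- pick(region_a)
  gb <- pick(region_b)
  sa <- structure(.summary_of(ga), class = "anisotropy_summary")
  sb <- structure(.summary_of(gb), class = "anisotropy_summary")
  out <- list(summaries = setNames(list(sa, sb),
                                   as.character(c(region_a, region_b))),
              difference_of_means = sa$mean - sb$mean,
              region_a = as.character(region_a),
              region_b = as.character(region_b))
  structure(out, class = "region_contrast")
}

#' @export
print.axis_summary <- function(x, ...) {
  cat("<axis_summary> total", x$total, "vectors:",
      paste(sprintf("%s %.1f%%", names(x$counts), 100 * x$fractions),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.anisotropy_summary <- function(x, ...) {
  cat(sprintf("<anisotropy_summary> mean %.3f median %.3f sd %.3f (n = %d)\n",
              x$mean, x$median, x$sd, x$n))
  invisible(x)
}

#' @export
print.region_contrast <- function(x, ...) {
  cat(sprintf("<region_contrast> mean(%s) - mean(%s) = %.3f\n",
              x$region_a, x$region_b, x$difference_of_means))
  invisible(x)
}

#' @export
print.plane_histogram <- function(x, ...) {
  cat("<plane_histogram>", x$plane, "with", length(x$counts), "bins,",
      sum(x$counts), "in-plane +", x$excluded, "excluded\n")
  invisible(x)
}
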