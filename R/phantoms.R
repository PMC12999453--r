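# Synthetic phantom generators with known ground truth.
#
# These stand in for real segmented micro-CT volumes in every validation
# test: each generator records the orientation/volume-fraction truth it
# was built from, so downstream fabric estimates can be checked against
# a known answer.

# counter-based per-fiber seed: adding fibers never reshuffles earlier
# ones; three Lehmer rounds scramble the counter so neighbouring fibers
# get decorrelated generator states
.fiber_seed <- function(seed, i) {
  x <- (seed %% 2147483647) + 1
  x <- (x * 48271 + i) %% 2147483647
  x <- (x * 48271 + 1) %% 2147483647
  x <- (x * 48271 + 1) %% 2147483647
  as.integer(x)
}

.axis_index <- function(axis) match(axis, .anat_axes)

#' Specification of a synthetic fiber/lattice phantom
#'
#' Validated parameter record for [generate_phantom()].  Kinds:
#' \describe{
#'   \item{parallel_fibers}{bundles of tubular fibers along
#'     `primary_axis`, each centerline tilted by at most
#'     `orientation_jitter_deg`.}
#'   \item{crossed_fibers}{volume tiled into cubic blocks of
#'     `block_edge_vox`; each block holds one parallel family, the
#'     primary family occupying `round(mixing_fraction * n_blocks)`
#'     blocks.}
#'   \item{isotropic_blobs}{Boolean model of spheres with random
#'     centers.}
#'   \item{trabecular}{Gaussian-smoothed random field thresholded to the
#'     target volume fraction; smoothing is stretched by `stretch` along
#'     `primary_axis` to impose a preferred strut orientation.}
#' }
#'
#' @param kind One of `"parallel_fibers"`, `"crossed_fibers"`,
#'   `"isotropic_blobs"`, `"trabecular"`.
#' @param shape Integer 3-vector of voxels per axis (each >= 16).
#' @param spacing_um Voxel spacing in micrometres.
#' @param fiber_radius_vox Fiber/sphere radius (trabecular: strut scale)
#'   in voxels.
#' @param target_volume_fraction Material fraction in (0, 0.7]; higher
#'   fractions merge fibers and void the orientation ground truth.
#' @param primary_axis,secondary_axis Anatomical axes `"X"|"Y"|"Z"`;
#'   `secondary_axis` (crossed only) must differ from `primary_axis`.
#' @param mixing_fraction Fraction of blocks given to the primary family
#'   (crossed only).
#' @param block_edge_vox Cubic block edge (crossed only); keep it larger
#'   than the analysis window for clean per-window ground truth.
#' @param orientation_jitter_deg Maximum centerline tilt from
#'   `primary_axis`, degrees.
#' @param stretch Anisotropy stretch of the trabecular smoothing kernel
#'   along `primary_axis` (>= 1; 1 = isotropic lattice).
#' @param seed Non-negative integer seed; the same spec and seed
#'   reproduce the volume bit for bit.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("parallel_fibers", "crossed_fibers",
                                  "isotropic_blobs", "trabecular"),
                         shape = c(128L, 128L, 128L),
                         spacing_um = 1,
                         fiber_radius_vox = 4,
                         target_volume_fraction = 0.3,
                         primary_axis = "X",
                         secondary_axis = NULL,
                         mixing_fraction = 0.5,
                         block_edge_vox = 64L,
                         orientation_jitter_deg = 0,
                         stretch = 1,
                         seed = 0L) {
  kind <- match.arg(kind)
  if (!is.numeric(shape) || length(shape) != 3L || any(shape < 16) ||
      any(shape != round(shape)))
    stop("invalid phantom spec: shape must be 3 integers >= 16",
         call. = FALSE)
  check_spacing(spacing_um)
  if (!is.numeric(fiber_radius_vox) || fiber_radius_vox <= 0)
    stop("invalid phantom spec: fiber_radius_vox must be positive",
         call. = FALSE)
  if (!is.numeric(target_volume_fraction) ||
      target_volume_fraction <= 0 || target_volume_fraction > 0.7)
    stop("invalid phantom spec: target_volume_fraction must lie in (0, 0.7]",
         call. = FALSE)
  if (!primary_axis %in% .anat_axes)
    stop("invalid phantom spec: primary_axis must be X, Y or Z",
         call. = FALSE)
  if (kind == "crossed_fibers") {
    if (is.null(secondary_axis) || !secondary_axis %in% .anat_axes ||
        secondary_axis == primary_axis)
      stop("invalid phantom spec: secondary_axis must be an axis distinct ",
           "from primary_axis", call. = FALSE)
    if (!is.numeric(mixing_fraction) || mixing_fraction < 0 ||
        mixing_fraction > 1)
      stop("invalid phantom spec: mixing_fraction must lie in [0, 1]",
           call. = FALSE)
    if (!is.numeric(block_edge_vox) || block_edge_vox < 1 ||
        block_edge_vox != round(block_edge_vox))
      stop("invalid phantom spec: block_edge_vox must be a positive integer",
           call. = FALSE)
  }
  if (!is.numeric(orientation_jitter_deg) || orientation_jitter_deg < 0)
    stop("invalid phantom spec: orientation_jitter_deg must be >= 0",
         call. = FALSE)
  if (!is.numeric(stretch) || stretch < 1)
    stop("invalid phantom spec: stretch must be >= 1", call. = FALSE)
  if (!is.numeric(seed) || seed < 0 || seed != round(seed))
    stop("invalid phantom spec: seed must be a non-negative integer",
         call. = FALSE)
  structure(list(kind = kind, shape = as.integer(shape),
                 spacing_um = spacing_um,
                 fiber_radius_vox = fiber_radius_vox,
                 target_volume_fraction = target_volume_fraction,
                 primary_axis = primary_axis,
                 secondary_axis = secondary_axis,
                 mixing_fraction = mixing_fraction,
                 block_edge_vox = as.integer(block_edge_vox),
                 orientation_jitter_deg = orientation_jitter_deg,
                 stretch = stretch, seed = as.integer(seed)),
            class = "phantom_spec")
}

# rasterize one straight fiber (per-slice discs along `axis`) into mask;
# returns the updated mask and the number of newly set voxels
.add_fiber <- function(mask, axis, c1, c2, s1, s2, radius) {
  dims <- dim(mask)
  L <- dims[axis]
  perp <- setdiff(1:3, axis)
  d1 <- dims[perp[1]]; d2 <- dims[perp[2]]
  mid <- (L - 1) / 2
  added <- 0L
  for (x in seq_len(L)) {
    cc1 <- c1 + (x - 1 - mid) * s1
    cc2 <- c2 + (x - 1 - mid) * s2
    i1 <- max(0, floor(cc1 - radius)):min(d1 - 1, ceiling(cc1 + radius))
    i2 <- max(0, floor(cc2 - radius)):min(d2 - 1, ceiling(cc2 + radius))
    if (i1[1] > i1[length(i1)] || i2[1] > i2[length(i2)]) next
    disc <- outer((i1 - cc1)^2, (i2 - cc2)^2, "+") <= radius^2
    if (!any(disc)) next
    idx <- vector("list", 3)
    idx[[axis]] <- x
    idx[[perp[1]]] <- i1 + 1L
    idx[[perp[2]]] <- i2 + 1L
    cur <- mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    # reshape disc into the array-order layout of the extracted slab
    sl <- array(FALSE, dim = c(length(idx[[1]]), length(idx[[2]]),
                               length(idx[[3]])))
    if (axis == 1) sl[1, , ] <- disc
    else if (axis == 2) sl[, 1, ] <- disc
    else sl[, , 1] <- disc
    new <- sl & !cur
    if (any(new)) {
      mask[idx[[1]], idx[[2]], idx[[3]]] <- cur | sl
      added <- added + sum(new)
    }
  }
  list(mask = mask, added = added)
}

.gen_parallel <- function(dims, axis, radius, target_vf, jitter_deg, seed,
                          seed_offset = 0) {
  mask <- array(FALSE, dim = dims)
  L <- dims[axis]
  perp <- setdiff(1:3, axis)
  target_vox <- round(target_vf * prod(dims))
  fiber_vol <- pi * radius^2 * L
  dirs <- NULL
  if (target_vf * prod(dims) < 0.5 * fiber_vol) {
    return(list(mask = mask, directions = matrix(numeric(0), 0, 3)))
  }
  cnt <- 0L
  i <- 0L
  dirs <- list()
  while (cnt < target_vox && i < 100000L) {
    i <- i + 1L
    set.seed(.fiber_seed(seed, seed_offset + i))
    c1 <- runif(1, 0, dims[perp[1]] - 1)
    c2 <- runif(1, 0, dims[perp[2]] - 1)
    theta <- runif(1, 0, jitter_deg) * pi / 180
    az <- runif(1, 0, 2 * pi)
    s1 <- tan(theta) * cos(az)
    s2 <- tan(theta) * sin(az)
    res <- .add_fiber(mask, axis, c1, c2, s1, s2, radius)
    mask <- res$mask
    cnt <- cnt + res$added
    d <- numeric(3)
    d[axis] <- 1
    d[perp[1]] <- s1
    d[perp[2]] <- s2
    dirs[[i]] <- d / sqrt(sum(d^2))
  }
  list(mask = mask, directions = do.call(rbind, dirs))
}

.gen_blobs <- function(dims, radius, target_vf, seed) {
  mask <- array(FALSE, dim = dims)
  target_vox <- round(target_vf * prod(dims))
  sphere_vol <- 4 / 3 * pi * radius^3
  if (target_vf * prod(dims) < 0.5 * sphere_vol) return(mask)
  cnt <- 0L
  i <- 0L
  while (cnt < target_vox && i < 200000L) {
    i <- i + 1L
    set.seed(.fiber_seed(seed, i))
    ctr <- runif(3, 0, dims - 1)
    rng <- lapply(1:3, function(k)
      max(0, floor(ctr[k] - radius)):min(dims[k] - 1, ceiling(ctr[k] + radius)))
    dd <- outer(outer((rng[[1]] - ctr[1])^2, (rng[[2]] - ctr[2])^2, "+"),
                (rng[[3]] - ctr[3])^2, "+")
    sph <- dd <= radius^2
    cur <- mask[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L]
    new <- sph & !cur
    if (any(new)) {
      mask[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L] <- cur | sph
      cnt <- cnt + sum(new)
    }
  }
  mask
}

.gen_trabecular <- function(dims, sigma, target_vf, axis, stretch, seed) {
  set.seed(as.integer(seed %% 2147483647))
  noise <- array(rnorm(prod(dims)), dim = dims)
  sig <- rep(sigma, 3)
  if (stretch > 1) sig[axis] <- sigma * stretch
  # frequency-domain Gaussian smoothing (circular boundary is fine for a
  # random texture)
  att <- lapply(1:3, function(k) {
    n <- dims[k]
    f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
    exp(-2 * pi^2 * sig[k]^2 * f^2)
  })
  A <- outer(outer(att[[1]], att[[2]]), att[[3]])
  sm <- Re(fft(fft(noise) * A, inverse = TRUE)) / prod(dims)
  thr <- quantile(sm, 1 - target_vf, names = FALSE)
  array(sm >= thr, dim = dims)
}

#' Generate a synthetic phantom volume
#'
#' Builds the binary mask described by a [phantom_spec()] together with
#' its ground-truth record.  Fibers are rasterized as hard cylinders
#' (voxel center within the radius of the centerline); overlap within a
#' family is allowed.  Fibers/spheres are added until the realized
#' volume fraction reaches the target, so the realized fraction lands
#' within about one fiber volume (well inside +/- 0.05 absolute at the
#' default sizes); a target below half of one fiber volume yields an
#' empty mask (the zero-fraction limit).
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_volume`: list with `mask` (logical 3D array),
#'   `labels` (`NULL` here; see [make_disc_phantom()]), `spacing_um`,
#'   `axis_map` (identity), and `truth` (kind, per-region dominant axis
#'   or `"isotropic"`, nominal volume fraction, seed, and generator
#'   details such as per-fiber directions or the crossed block grid).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("spec must be a phantom_spec", call. = FALSE)
  dims <- spec$shape
  axis <- .axis_index(spec$primary_axis)
  truth <- list(kind = spec$kind, seed = spec$seed,
                nominal_volume_fraction = spec$target_volume_fraction)

  if (spec$kind == "parallel_fibers") {
    g <- .gen_parallel(dims, axis, spec$fiber_radius_vox,
                       spec$target_volume_fraction,
                       spec$orientation_jitter_deg, spec$seed)
    mask <- g$mask
    ax <- numeric(3); ax[axis] <- 1
    truth$dominant_axis <- ax
    truth$fiber_directions <- g$directions
  } else if (spec$kind == "isotropic_blobs") {
    mask <- .gen_blobs(dims, spec$fiber_radius_vox,
                       spec$target_volume_fraction, spec$seed)
    truth$dominant_axis <- "isotropic"
  } else if (spec$kind == "trabecular") {
    mask <- .gen_trabecular(dims, spec$fiber_radius_vox,
                            spec$target_volume_fraction, axis,
                            spec$stretch, spec$seed)
    truth$dominant_axis <- if (spec$stretch > 1) {
      ax <- numeric(3); ax[axis] <- 1; ax
    } else "isotropic"
    truth$stretch <- spec$stretch
  } else { # crossed_fibers
    be <- spec$block_edge_vox
    starts <- lapply(dims, function(n) seq(1L, n, by = be))
    grid <- expand.grid(i = starts[[1]], j = starts[[2]], k = starts[[3]])
    nb <- nrow(grid)
    n_primary <- round(spec$mixing_fraction * nb)
    set.seed(as.integer(spec$seed %% 2147483647))
    ord <- sample.int(nb)
    family <- rep(2L, nb)                 # 1 = primary, 2 = secondary
    family[ord[seq_len(n_primary)]] <- 1L
    ax2 <- .axis_index(spec$secondary_axis)
    mask <- array(FALSE, dim = dims)
    for (b in seq_len(nb)) {
      lo <- c(grid$i[b], grid$j[b], grid$k[b])
      hi <- pmin(lo + be - 1L, dims)
      bdims <- hi - lo + 1L
      fam_axis <- if (family[b] == 1L) axis else ax2
      g <- .gen_parallel(bdims, fam_axis, spec$fiber_radius_vox,
                         spec$target_volume_fraction,
                         spec$orientation_jitter_deg, spec$seed,
                         seed_offset = b * 1000L)
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- g$mask
    }
    a1 <- numeric(3); a1[axis] <- 1
    a2 <- numeric(3); a2[ax2] <- 1
    truth$primary_axis <- a1
    truth$secondary_axis <- a2
    truth$mixing_fraction <- spec$mixing_fraction
    truth$block_edge_vox <- be
    truth$block_origin <- as.matrix(grid)
    truth$block_family <- family
  }
  structure(list(mask = mask, labels = NULL, spacing_um = spec$spacing_um,
                 axis_map = c("X", "Y", "Z"), truth = truth, spec = spec),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("<phantom_volume> ", x$truth$kind %||% "disc", ", ",
      paste(dim(x$mask), collapse = " x "), " voxels, fraction ",
      signif(mean(x$mask), 3), ", seed ", x$truth$seed, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
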