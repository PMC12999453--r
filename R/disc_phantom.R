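# Biconcave disc phantom: a superellipse footprint in the XY plane with
# a biconcave thickness profile along Z, circumferentially aligned fibers
# in a peripheral rim, and a center whose fiber orientations interpolate
# between uniformly random and circumferential.

# footprint constants (implementation contract, documented here):
# superellipse exponent p = 2.5; in-plane semi-axes 0.46 * shape;
# half-thickness profile H(rho) = h_c + (h_r - h_c) * rho^2 with
# h_c = 0.18 * nz (center) and h_r = 0.45 * nz (rim), so the center is
# thinner than the peripheral band (biconcave);
# per-region fiber fill fraction 0.35; center fiber length = 8 * radius;
# rim bundles follow the contour for ~.disc_rim_arc voxels of arc.
.disc_p <- 2.5
.disc_semi <- 0.46
.disc_hc <- 0.18
.disc_hr <- 0.45
.disc_fill <- 0.35
.disc_rim_arc <- 64
.disc_rim_step <- 4

#' Specification of the biconcave disc phantom
#'
#' @param shape Integer 3-vector (X, Y, Z voxels); the default is wider
#'   laterally (X) than ventrodorsally (Y), like a fibrocartilage disc.
#' @param spacing_um Voxel spacing in micrometres.
#' @param rim_width_fraction Radial width of the peripheral rim as a
#'   fraction of the in-plane radius, in (0, 0.5).
#' @param rim_fiber_radius_vox Fiber radius in voxels (used in both
#'   regions).
#' @param center_alignment Blend of the central fiber orientations
#'   between uniformly random (0) and the local circumferential
#'   direction (1).
#' @param seed Non-negative integer seed.
#' @return A validated `disc_phantom_spec` list.
#' @export
disc_phantom_spec <- function(shape = c(192L, 128L, 48L),
                              spacing_um = 1,
                              rim_width_fraction = 0.25,
                              rim_fiber_radius_vox = 2,
                              center_alignment = 0,
                              seed = 0L) {
  if (!is.numeric(shape) || length(shape) != 3L || any(shape < 16) ||
      any(shape != round(shape)))
    stop("invalid disc spec: shape must be 3 integers >= 16", call. = FALSE)
  check_spacing(spacing_um)
  if (!is.numeric(rim_width_fraction) || rim_width_fraction <= 0 ||
      rim_width_fraction >= 0.5)
    stop("invalid disc spec: rim_width_fraction must lie in (0, 0.5)",
         call. = FALSE)
  if (!is.numeric(rim_fiber_radius_vox) || rim_fiber_radius_vox <= 0)
    stop("invalid disc spec: rim_fiber_radius_vox must be positive",
         call. = FALSE)
  if (!is.numeric(center_alignment) || center_alignment < 0 ||
      center_alignment > 1)
    stop("invalid disc spec: center_alignment must lie in [0, 1]",
         call. = FALSE)
  if (!is.numeric(seed) || seed < 0 || seed != round(seed))
    stop("invalid disc spec: seed must be a non-negative integer",
         call. = FALSE)
  structure(list(shape = as.integer(shape), spacing_um = spacing_um,
                 rim_width_fraction = rim_width_fraction,
                 rim_fiber_radius_vox = rim_fiber_radius_vox,
                 center_alignment = center_alignment,
                 seed = as.integer(seed)),
            class = "disc_phantom_spec")
}

# radial coordinate rho and circumferential unit tangent at (x, y),
# 0-based voxel coordinates
.disc_rho <- function(x, y, cx, cy, a, b) {
  ((abs(x - cx) / a)^.disc_p + (abs(y - cy) / b)^.disc_p)^(1 / .disc_p)
}

# polyline along the superellipse level curve through (x, y), centered
# there, with total arc length ~arc; points are (x, y) pairs
.disc_contour_polyline <- function(x, y, cx, cy, a, b, arc, step) {
  u <- (x - cx) / a
  v <- (y - cy) / b
  rho <- (abs(u)^.disc_p + abs(v)^.disc_p)^(1 / .disc_p)
  if (rho < 1e-6) return(NULL)
  # superellipse parameter of the point: |cos phi|^(2/p) etc.
  phi <- atan2(sign(v) * abs(v)^(.disc_p / 2), sign(u) * abs(u)^(.disc_p / 2))
  pt <- function(ph) {
    c(cx + a * rho * sign(cos(ph)) * abs(cos(ph))^(2 / .disc_p),
      cy + b * rho * sign(sin(ph)) * abs(sin(ph))^(2 / .disc_p))
  }
  # walk around the contour, choosing the parameter step locally so each
  # segment has ~`step` voxels of arc; arc = Inf closes the full ring
  pts <- list(pt(phi))
  ph <- phi
  travelled <- 0
  limit <- if (is.finite(arc)) arc else .Machine$double.xmax
  # strict-inequality guard: (phi + 2*pi) - phi can round below 2*pi
  while (travelled < limit && (ph - phi) < 2 * pi - 1e-9 &&
         length(pts) < 2000L) {
    speed <- sqrt(sum((pt(ph + 1e-4) - pt(ph))^2)) / 1e-4
    if (!is.finite(speed) || speed < 1e-9) speed <- rho * sqrt(a * b)
    # the parameter speed diverges near the axes (2/p < 1); floor the
    # step so the walk always advances
    ph <- min(ph + max(step / speed, 2 * pi / 720), phi + 2 * pi)
    pts[[length(pts) + 1L]] <- pt(ph)
    travelled <- travelled + step
  }
  do.call(rbind, pts)
}

.disc_tangent <- function(x, y, cx, cy, a, b) {
  u <- (x - cx) / a
  v <- (y - cy) / b
  gx <- .disc_p * sign(u) * abs(u)^(.disc_p - 1) / a
  gy <- .disc_p * sign(v) * abs(v)^(.disc_p - 1) / b
  t <- c(-gy, gx, 0)
  n <- sqrt(sum(t^2))
  if (n < 1e-9) {
    az <- runif(1, 0, 2 * pi)
    return(c(cos(az), sin(az), 0))
  }
  t / n
}

# linear voxel indices of a capsule (cylinder with spherical caps) of
# radius r between p0 and p1
.capsule_indices <- function(dims, p0, p1, r) {
  lo <- pmax(0, floor(pmin(p0, p1) - r))
  hi <- pmin(dims - 1, ceiling(pmax(p0, p1) + r))
  if (any(lo > hi)) return(integer(0))
  rng <- lapply(1:3, function(k) lo[k]:hi[k])
  nx <- length(rng[[1]]); ny <- length(rng[[2]]); nz <- length(rng[[3]])
  X <- array(rng[[1]], dim = c(nx, ny, nz))
  Y <- array(rep(rng[[2]], each = nx), dim = c(nx, ny, nz))
  Z <- array(rep(rng[[3]], each = nx * ny), dim = c(nx, ny, nz))
  seg <- p1 - p0
  len2 <- sum(seg^2)
  if (len2 == 0) {
    d2 <- (X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2
  } else {
    t <- ((X - p0[1]) * seg[1] + (Y - p0[2]) * seg[2] +
          (Z - p0[3]) * seg[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (X - (p0[1] + t * seg[1]))^2 + (Y - (p0[2] + t * seg[2]))^2 +
          (Z - (p0[3] + t * seg[3]))^2
  }
  cap <- d2 <= r^2
  if (!any(cap)) return(integer(0))
  # linear index = 1 + x + nx*(y + ny*z) over the full array
  (X[cap] + 1L) + dims[1] * (Y[cap] + dims[2] * Z[cap])
}

# rasterize a polyline of capsules into `mask`, restricted to voxels
# where `region` is TRUE; single mask write per polyline
.add_polyline <- function(mask, region, pts, r) {
  dims <- dim(mask)
  idx <- unlist(lapply(seq_len(nrow(pts) - 1L), function(s)
    .capsule_indices(dims, pts[s, ], pts[s + 1L, ], r)))
  if (length(idx) == 0) return(list(mask = mask, added = 0L))
  idx <- unique(idx)
  idx <- idx[region[idx] & !mask[idx]]
  mask[idx] <- TRUE
  list(mask = mask, added = length(idx))
}

#' Generate the biconcave disc phantom
#'
#' Builds a disc-shaped label map (rim = 1, center = 2) and a fiber mask
#' inside it.  Rim fibers are long circumferential bundles that follow
#' the disc outline (polyline capsules along the superellipse contour,
#' with a small random vertical drift); center fibers are short capsules
#' whose orientations are drawn uniformly at random on the sphere and
#' blended toward the local circumferential direction by
#' `center_alignment`.  Each region is filled to a fraction of 0.35 of
#' its voxels.  The sampled center-region directions are stored in the truth
#' record so orientation statistics can be validated against them.
#'
#' @param spec A [disc_phantom_spec()].
#' @return A `phantom_volume` whose `labels` field holds the region map
#'   (legend: 1 = rim, 2 = center) and whose `truth` records the
#'   circumferential rim, the center alignment level, and the sampled
#'   center fiber directions.
#' @export
make_disc_phantom <- function(spec) {
  if (!inherits(spec, "disc_phantom_spec"))
    stop("spec must be a disc_phantom_spec", call. = FALSE)
  dims <- spec$shape
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2; cz <- (nz - 1) / 2
  a <- .disc_semi * nx; b <- .disc_semi * ny
  h_c <- .disc_hc * nz; h_r <- .disc_hr * nz

  xs <- 0:(nx - 1); ys <- 0:(ny - 1)
  rho <- outer(xs, ys, function(x, y) .disc_rho(x, y, cx, cy, a, b))
  H <- h_c + (h_r - h_c) * pmin(rho, 1)^2
  inside2d <- rho <= 1
  rim2d <- inside2d & rho >= 1 - spec$rim_width_fraction

  labels <- array(0L, dim = dims)
  for (k in seq_len(nz)) {
    inz <- inside2d & abs(k - 1 - cz) <= H
    sl <- array(0L, dim = c(nx, ny))
    sl[inz & rim2d] <- 1L
    sl[inz & !rim2d] <- 2L
    labels[, , k] <- sl
  }

  mask <- array(FALSE, dim = dims)
  r <- spec$rim_fiber_radius_vox
  flen <- 8 * r
  center_dirs <- list()

  for (region_id in 1:2) {
    region <- labels == region_id
    idx <- which(region)
    nreg <- length(idx)
    if (nreg == 0) next
    target <- round(.disc_fill * nreg)
    coord <- arrayInd(idx, dims) - 1L
    cnt <- 0L
    i <- 0L
    off <- if (region_id == 1L) 0 else 500000
    while (cnt < target && i < 60000L) {
      i <- i + 1L
      set.seed(.fiber_seed(spec$seed, off + i))
      p <- coord[sample.int(nreg, 1), ] + runif(3, -0.5, 0.5)
      tang <- .disc_tangent(p[1], p[2], cx, cy, a, b)
      if (region_id == 1L) {
        # circumferential reinforcement ring: a closed polyline along
        # the disc outline at this point's radial level, with a gentle
        # vertical undulation
        poly <- .disc_contour_polyline(p[1], p[2], cx, cy, a, b,
                                       Inf, .disc_rim_step)
        if (is.null(poly)) next
        ns <- nrow(poly)
        amp <- rnorm(1, 0, 1)
        phase <- runif(1, 0, 2 * pi)
        zs <- p[3] + amp * sin(2 * pi * (1:ns) / ns + phase)
        res <- .add_polyline(mask, region, cbind(poly, zs), r)
        mask <- res$mask
        cnt <- cnt + res$added
        next
      } else {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        alpha <- spec$center_alignment
        if (alpha > 0) {
          tt <- if (sum(u * tang) < 0) -tang else tang
          d <- (1 - alpha) * u + alpha * tt
          d <- d / sqrt(sum(d^2))
        } else {
          d <- u
        }
        center_dirs[[length(center_dirs) + 1L]] <- d
      }
      res <- .add_polyline(mask, region,
                           rbind(p - flen / 2 * d, p + flen / 2 * d), r)
      mask <- res$mask
      cnt <- cnt + res$added
    }
  }

  truth <- list(kind = "disc", seed = spec$seed,
                regions = list(
                  rim = list(orientation = "circumferential",
                             anisotropic = TRUE),
                  center = list(alignment = spec$center_alignment)),
                fill_fraction = .disc_fill,
                center_directions = do.call(rbind, center_dirs),
                rim_width_fraction = spec$rim_width_fraction)
  structure(list(mask = mask, labels = labels,
                 legend = c("1" = "rim", "2" = "center"),
                 spacing_um = spec$spacing_um,
                 axis_map = c("X", "Y", "Z"), truth = truth, spec = spec),
            class = "phantom_volume")
}
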