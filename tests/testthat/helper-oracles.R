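# Independent reference implementations and fixture builders used across
# the suite.  These share the documented sampling geometry with the
# package but are written naively (plain R loops, rle, brute-force
# enumeration) so they exercise none of the package's code paths.

# naive per-line run-length MIL reference
mil_oracle <- function(mask, spacing_um, directions, line_spacing_vox) {
  dims <- dim(mask)
  nd <- nrow(directions)
  counts <- integer(nd)
  samples <- numeric(nd)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(intercept_count = counts,
                total_material_length_um = samples))
  lo <- apply(idx, 2, min) - 1
  hi <- apply(idx, 2, max) - 1
  ctr <- (lo + hi) / 2
  ext <- hi - lo + 1
  R <- 0.5 * sqrt(sum(ext^2))
  mmax <- floor(R / line_spacing_vox)
  tmax <- floor(R / 0.5)
  tvals <- (-tmax:tmax) * 0.5
  for (s in seq_len(nd)) {
    d <- as.numeric(directions[s, ])
    ad <- abs(d)
    k0 <- if (ad[1] <= ad[2] && ad[1] <= ad[3]) 1 else if (ad[2] <= ad[3]) 2 else 3
    w <- c(0, 0, 0); w[k0] <- 1
    u <- c(d[2] * w[3] - d[3] * w[2],
           d[3] * w[1] - d[1] * w[3],
           d[1] * w[2] - d[2] * w[1])
    u <- u / sqrt(sum(u^2))
    v <- c(d[2] * u[3] - d[3] * u[2],
           d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    nrun <- 0L; nmat <- 0L
    for (ia in -mmax:mmax) for (ib in -mmax:mmax) {
      a <- ia * line_spacing_vox; b <- ib * line_spacing_vox
      bx <- ctr[1] + a * u[1] + b * v[1]
      by <- ctr[2] + a * u[2] + b * v[2]
      bz <- ctr[3] + a * u[3] + b * v[3]
      i <- floor(bx + tvals * d[1] + 0.5)
      j <- floor(by + tvals * d[2] + 0.5)
      k <- floor(bz + tvals * d[3] + 0.5)
      ok <- i >= 0 & i < dims[1] & j >= 0 & j < dims[2] & k >= 0 & k < dims[3]
      mat <- logical(length(tvals))
      if (any(ok)) mat[ok] <- mask[cbind(i[ok] + 1, j[ok] + 1, k[ok] + 1)]
      r <- rle(mat)
      nrun <- nrun + sum(r$values)
      nmat <- nmat + sum(mat)
    }
    counts[s] <- nrun
    samples[s] <- nmat
  }
  list(intercept_count = counts,
       total_material_length_um = samples * 0.5 * spacing_um)
}

# brute-force largest-inscribed-sphere thickness (voxel units):
# exhaustive distance minimization and sphere enumeration
thickness_oracle_vox <- function(mask) {
  dims <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  th <- array(NA_real_, dims)
  r <- numeric(nrow(fg))
  for (ci in seq_len(nrow(fg))) {
    dif <- sweep(bg, 2, fg[ci, ])
    r[ci] <- sqrt(min(rowSums(dif^2))) - 0.5
  }
  th[mask] <- 0
  for (ci in seq_len(nrow(fg))) {
    dif <- sweep(fg, 2, fg[ci, ])
    inside <- rowSums(dif^2) < r[ci]^2
    cover <- fg[inside, , drop = FALSE]
    for (q in seq_len(nrow(cover))) {
      v <- cover[q, ]
      th[v[1], v[2], v[3]] <- max(th[v[1], v[2], v[3]], 2 * r[ci])
    }
  }
  th
}

# voxel-centered solid sphere of the given radius
sphere_mask <- function(radius, margin = 3) {
  n <- 2 * (radius + margin) + 1
  off <- (0:(n - 1)) - (radius + margin)
  array(outer(outer(off^2, off^2, "+"), off^2, "+") <= radius^2,
        c(n, n, n))
}

# voxel-centered solid cylinder along array dim 3
cylinder_mask <- function(radius, length, margin = 3) {
  n <- 2 * (radius + margin) + 1
  off <- (0:(n - 1)) - (radius + margin)
  disc <- outer(off^2, off^2, "+") <= radius^2
  array(rep(disc, length), c(n, n, length))
}

# periodic slabs along array dim 3: `period` material then `period` void,
# beginning and ending with material so void slabs are interior
slab_mask <- function(period = 8, bands = 5, side = 40) {
  nz <- period * bands
  m <- array(FALSE, c(side, side, nz))
  for (k in seq_len(nz))
    if (((k - 1) %/% period) %% 2 == 0) m[, , k] <- TRUE
  m
}

# 90-degree grid rotations (proper rotations of the array about each
# anatomical axis, for axis_map = identity), with the matching rotation
# matrices for vector data
rot90_z <- function(m) {
  A <- aperm(m, c(2, 1, 3))
  A[rev(seq_len(dim(A)[1])), , , drop = FALSE]
}
rot90_x <- function(m) {
  A <- aperm(m, c(1, 3, 2))
  A[, rev(seq_len(dim(A)[2])), , drop = FALSE]
}
rot90_y <- function(m) {
  A <- aperm(m, c(3, 2, 1))
  A[, , rev(seq_len(dim(A)[3])), drop = FALSE]
}
rotmat_z <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
rotmat_x <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)
rotmat_y <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)

# smallest angle (degrees) between two axial unit vectors
axial_angle_deg <- function(u, v) {
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}
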