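test_that("thickness of canonical solids matches the analytic diameters", {
  th <- local_thickness(sphere_mask(10), 1)
  expect_gte(max(th$thickness_um, na.rm = TRUE), 19)
  expect_lte(max(th$thickness_um, na.rm = TRUE), 21)

  cyl <- cylinder_mask(5, 30)
  thc <- local_thickness(cyl, 1)
  mid <- thc$thickness_um[9, 9, 15]     # on the axis, mid-length
  expect_gte(mid, 9)
  expect_lte(mid, 11)

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  ths <- local_thickness(single, 2.5)
  expect_equal(ths$thickness_um[3, 3, 3], 2.5)   # one voxel diameter
})

test_that("thickness is defined exactly on the mask and >= one voxel", {
  set.seed(1)
  mask <- array(runif(16^3) < 0.3, c(16, 16, 16))
  th <- local_thickness(mask, 3)
  expect_identical(!is.na(th$thickness_um), mask)
  expect_gte(min(th$thickness_um, na.rm = TRUE), 3)
})

test_that("slab separation matches the gap width; roi errors without void", {
  slab <- slab_mask(8, 5, 40)
  roi <- array(TRUE, dim(slab))
  sep <- separation(slab, roi, 1)
  s <- summary(sep)
  expect_gte(s$mean, 7)
  expect_lte(s$mean, 9)
  expect_error(separation(slab, slab, 1), "void")
  expect_error(local_thickness(array(FALSE, c(8, 8, 8)), 1), "empty")
})

test_that("thickness of the slabs equals separation of their complement", {
  # material and void slabs both interior: 40 = void 8 | mat 8 | ... | void 8
  m <- array(FALSE, c(24, 24, 40))
  for (k in 1:40) if (((k - 1) %/% 8) %% 2 == 1) m[, , k] <- TRUE
  roi <- array(TRUE, dim(m))
  th <- summary(local_thickness(m, 1))
  sp <- summary(separation(!m & roi, roi, 1))   # complement's separation
  expect_equal(th$mean, sp$mean)
})

test_that("thickness equals the brute-force inscribed-sphere oracle", {
  set.seed(6)
  for (rep in 1:3) {
    mask <- array(FALSE, c(14, 14, 14))
    # a few random blobs
    for (b in 1:3) {
      c0 <- runif(3, 4, 10); r0 <- runif(1, 2, 4)
      g <- expand.grid(x = 1:14, y = 1:14, z = 1:14)
      inside <- (g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <= r0^2
      mask[as.matrix(g[inside, ])] <- TRUE
    }
    if (!any(mask) || all(mask)) next
    th <- local_thickness(mask, 1)$thickness_um
    ref <- thickness_oracle_vox(mask)
    expect_lt(max(abs(th - ref), na.rm = TRUE), 1e-9)
  }
})

test_that("dilation never decreases local thickness", {
  set.seed(12)
  mask <- sphere_mask(4, margin = 5)
  th0 <- local_thickness(mask, 1)$thickness_um
  # 6-neighborhood dilation
  d <- mask
  d[-1, , ] <- d[-1, , ] | mask[-dim(mask)[1], , ]
  d[-dim(mask)[1], , ] <- d[-dim(mask)[1], , ] | mask[-1, , ]
  d[, -1, ] <- d[, -1, ] | mask[, -dim(mask)[2], ]
  d[, -dim(mask)[2], ] <- d[, -dim(mask)[2], ] | mask[, -1, ]
  d[, , -1] <- d[, , -1] | mask[, , -dim(mask)[3]]
  d[, , -dim(mask)[3]] <- d[, , -dim(mask)[3]] | mask[, , -1]
  th1 <- local_thickness(d, 1)$thickness_um
  expect_true(all(th1[mask] >= th0[mask] - 1e-9))
})

test_that("tissue metrics report exact volume, extents and fabric anisotropy", {
  cube <- array(0L, c(12, 12, 12))
  cube[2:11, 2:11, 2:11] <- 1L
  m <- tissue_metrics(cube, label = 1L, spacing_um = 10, thickness = FALSE)
  expect_equal(m$volume_mm3, 1000 * 10^3 / 1e9)
  expect_equal(unname(m$extent_mm), rep(0.1, 3))
  expect_error(tissue_metrics(cube, label = 7L, spacing_um = 10), "absent")

  # volume is invariant under axis permutation
  m2 <- tissue_metrics(aperm(cube, c(3, 1, 2)), label = 1L, spacing_um = 10,
                       axis_map = c("Z", "X", "Y"), thickness = FALSE)
  expect_equal(m2$volume_mm3, m$volume_mm3)
  expect_equal(m2$extent_mm, m$extent_mm)

  tr <- generate_phantom(phantom_spec("trabecular", shape = c(64, 64, 64),
                                      target_volume_fraction = 0.25,
                                      fiber_radius_vox = 3,
                                      primary_axis = "Z", stretch = 3,
                                      seed = 9))
  mt <- tissue_metrics(tr$mask, spacing_um = 1,
                       roi = array(TRUE, dim(tr$mask)),
                       directions = sample_directions(64), thickness = FALSE)
  expect_lt(abs(mt$volume_fraction - 0.25), 0.05)
  expect_gt(mt$global_anisotropy, 0.2)
  expect_lt(axial_angle_deg(mt$global_fabric$eigenvectors[, 1], c(0, 0, 1)),
            10)
})
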