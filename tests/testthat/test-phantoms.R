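test_that("phantom spec validation names the offending field", {
  expect_error(phantom_spec(shape = c(8, 64, 64)), "shape")
  expect_error(phantom_spec(target_volume_fraction = 0.8),
               "target_volume_fraction")
  expect_error(phantom_spec(target_volume_fraction = 0), "target_volume_fraction")
  expect_error(phantom_spec("crossed_fibers", secondary_axis = "X",
                            primary_axis = "X"), "secondary_axis")
  expect_error(phantom_spec(orientation_jitter_deg = -1),
               "orientation_jitter_deg")
  expect_error(phantom_spec(seed = -1), "seed")
  expect_error(phantom_spec(fiber_radius_vox = 0), "fiber_radius_vox")
})

test_that("realized volume fractions land within 0.05 of the target", {
  cases <- list(
    phantom_spec("parallel_fibers", shape = c(64, 64, 64),
                 target_volume_fraction = 0.3, seed = 7),
    phantom_spec("isotropic_blobs", shape = c(64, 64, 64),
                 target_volume_fraction = 0.2, seed = 2),
    phantom_spec("trabecular", shape = c(64, 64, 64), fiber_radius_vox = 3,
                 target_volume_fraction = 0.25, seed = 3),
    phantom_spec("crossed_fibers", shape = c(64, 64, 64),
                 target_volume_fraction = 0.3, secondary_axis = "Y",
                 block_edge_vox = 32L, seed = 4))
  for (sp in cases) {
    ph <- generate_phantom(sp)
    expect_lt(abs(mean(ph$mask) - sp$target_volume_fraction), 0.05,
              label = sp$kind)
  }
})

test_that("a vanishing target fraction yields an empty mask", {
  for (kind in c("parallel_fibers", "isotropic_blobs")) {
    sp <- phantom_spec(kind, shape = c(32, 32, 32),
                       target_volume_fraction = 1e-6, seed = 1)
    ph <- generate_phantom(sp)
    expect_equal(sum(ph$mask), 0)
  }
})

test_that("identical spec and seed reproduce the mask bit for bit", {
  for (kind in c("parallel_fibers", "isotropic_blobs", "trabecular")) {
    sp <- phantom_spec(kind, shape = c(32, 32, 32),
                       target_volume_fraction = 0.3, fiber_radius_vox = 3,
                       seed = 99)
    expect_identical(generate_phantom(sp)$mask, generate_phantom(sp)$mask)
  }
})

test_that("parallel fiber centerlines respect the jitter bound", {
  sp <- phantom_spec("parallel_fibers", shape = c(48, 48, 48),
                     target_volume_fraction = 0.2,
                     orientation_jitter_deg = 2, seed = 13)
  ph <- generate_phantom(sp)
  dirs <- ph$truth$fiber_directions
  expect_gt(nrow(dirs), 0)
  dev <- acos(pmin(1, abs(dirs %*% ph$truth$dominant_axis))) * 180 / pi
  expect_true(all(dev <= 2 + 1e-9))
})

test_that("crossed blocks tile the volume with the requested family mixture", {
  sp <- phantom_spec("crossed_fibers", shape = c(64, 64, 64),
                     target_volume_fraction = 0.3, secondary_axis = "Z",
                     block_edge_vox = 32L, mixing_fraction = 0.5, seed = 21)
  ph <- generate_phantom(sp)
  fam <- ph$truth$block_family
  expect_equal(length(fam), 8)
  expect_equal(sum(fam == 1L), round(0.5 * 8))
  expect_equal(nrow(ph$truth$block_origin), 8)
})

test_that("the trabecular stretch imposes the declared dominant axis", {
  sp <- phantom_spec("trabecular", shape = c(64, 64, 64),
                     target_volume_fraction = 0.25, fiber_radius_vox = 3,
                     primary_axis = "Z", stretch = 3, seed = 5)
  ph <- generate_phantom(sp)
  expect_equal(ph$truth$dominant_axis, c(0, 0, 1))
  ft <- fit_fabric_tensor(compute_mil(ph$mask, 1, sample_directions(64), 2))
  expect_lt(axial_angle_deg(ft$eigenvectors[, 1], c(0, 0, 1)), 10)
  expect_gt(anisotropy_index(ft), 0.2)
})

test_that("parallel and slab phantoms give prolate and oblate fabric", {
  ph <- generate_phantom(phantom_spec("parallel_fibers", shape = c(64, 64, 64),
                                      target_volume_fraction = 0.3, seed = 7))
  ft <- fit_fabric_tensor(compute_mil(ph$mask, 1, sample_directions(64), 2))
  lam <- ft$eigenvalues_um
  expect_gt(lam[1], 2 * lam[2])            # rods: l1 >> l2 ~ l3
  expect_lt(lam[2], 2 * lam[3])
  slab <- slab_mask(8, 8, 64)
  fts <- fit_fabric_tensor(compute_mil(slab, 1, sample_directions(64), 2))
  lams <- fts$eigenvalues_um
  expect_gt(lams[2], 2 * lams[3])          # plates: l1 ~ l2 >> l3
  expect_lt(lams[1], 2 * lams[2])
})
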