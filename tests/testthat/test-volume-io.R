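test_that("a single set voxel survives the stack round trip at its index", {
  d <- withr::local_tempdir()
  arr <- array(0L, c(8, 16, 16))
  arr[3, 5, 11] <- 1L
  p <- file.path(d, "one.tif")
  write_volume_stack(arr, p, spacing_um = 2)
  v <- read_volume_stack(p)
  expect_equal(sum(v$data != 0), 1)
  expect_equal(which(v$data != 0, arr.ind = TRUE)[1, ],
               c(dim1 = 3L, dim2 = 5L, dim3 = 11L), ignore_attr = TRUE)
  expect_equal(v$spacing_um, 2)
})

test_that("phantom masks and label maps round-trip bit for bit", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec("isotropic_blobs",
                                      shape = c(24, 24, 24),
                                      target_volume_fraction = 0.2, seed = 1))
  p <- file.path(d, "mask.tif")
  write_volume_stack(ph$mask, p, spacing_um = 6.48)
  v <- read_volume_stack(p)
  expect_identical(array(v$data != 0, dim(v$data)), ph$mask)
  # binary masks are stored with values exactly 0/1
  expect_setequal(unique(as.vector(v$data)), c(0L, 1L))

  lm <- label_map(array(sample(0:3, 4 * 5 * 6, TRUE), c(4, 5, 6)),
                  c("1" = "bone", "2" = "cartilage", "3" = "disc"),
                  spacing_um = 6.48, axis_map = c("Z", "Y", "X"))
  pl <- file.path(d, "labels.tif")
  write_volume_stack(lm, pl)
  lm2 <- read_volume_stack(pl)
  expect_s3_class(lm2, "label_map")
  expect_identical(lm2$labels, lm$labels)
  expect_equal(lm2$axis_map, c("Z", "Y", "X"))
  expect_equal(lm2$legend, lm$legend)
})

test_that("an all-zero volume round-trips and spacing is never guessed", {
  d <- withr::local_tempdir()
  p <- file.path(d, "zero.tif")
  write_volume_stack(array(0L, c(4, 6, 6)), p, spacing_um = 1)
  v <- read_volume_stack(p)
  expect_true(all(v$data == 0))
  file.remove(paste0(p, ".json"))
  expect_error(read_volume_stack(p), "spacing")
})

test_that("slice directories read in lexicographic order; ragged stacks error", {
  d <- withr::local_tempdir()
  sd <- file.path(d, "slices")
  dir.create(sd)
  for (s in 1:5) {
    m <- matrix(0, 6, 7); m[1, 1] <- s / 255
    tiff::writeTIFF(m, file.path(sd, sprintf("slice_%03d.tif", s)),
                    bits.per.sample = 8L)
  }
  v <- read_volume_stack(sd, spacing_um = 1)
  expect_equal(dim(v$data), c(5, 6, 7))
  expect_equal(v$data[, 1, 1], 1:5)
  tiff::writeTIFF(matrix(0, 3, 3), file.path(sd, "slice_999.tif"),
                  bits.per.sample = 8L)
  expect_error(read_volume_stack(sd, spacing_um = 1), "inconsistent")
})

test_that("float volumes round-trip at float32-level fidelity", {
  d <- withr::local_tempdir()
  fv <- voxel_volume(array(rnorm(4 * 4 * 4) * 300 - 20, c(4, 4, 4)), 1.5)
  p <- file.path(d, "float.tif")
  write_volume_stack(fv, p)
  v <- read_volume_stack(p)
  expect_lt(max(abs(v$data - fv$data)) / diff(range(fv$data)), 1e-8)
})

test_that("field CSV export writes the exact schema and re-parses losslessly", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec("parallel_fibers", shape = c(32, 32, 32),
                                      target_volume_fraction = 0.3, seed = 7))
  f <- map_orientation_field(ph, window = window_spec(16L, 16L),
                             directions = sample_directions(32))
  p <- file.path(d, "field.csv")
  export_field_csv(f, p)
  lines <- readLines(p)
  expect_equal(length(lines), nrow(f) + 1)
  expect_equal(lines[1], paste(
    "cx_um,cy_um,cz_um,e1x,e1y,e1z,e2x,e2y,e2z,e3x,e3y,e3z",
    "l1_um,l2_um,l3_um,magnitude_um,anisotropy_index,material_fraction",
    sep = ","))
  back <- read_field_csv(p)
  for (cn in c("l1_um", "l2_um", "l3_um", "anisotropy_index"))
    expect_equal(back[[cn]], signif(f[[cn]], 9), tolerance = 1e-9)

  # an empty field exports the header only
  empty <- map_orientation_field(array(FALSE, c(16, 16, 16)), 1,
                                 window = window_spec(16L, 16L),
                                 directions = sample_directions(32))
  pe <- file.path(d, "empty.csv")
  export_field_csv(empty, pe)
  expect_equal(length(readLines(pe)), 1)
})

test_that("reading honors an explicit axis_map permutation", {
  d <- withr::local_tempdir()
  arr <- array(seq_len(3 * 4 * 5), c(3, 4, 5))
  p <- file.path(d, "perm.tif")
  write_volume_stack(arr, p, spacing_um = 1, axis_map = c("Z", "Y", "X"))
  v <- read_volume_stack(p)
  expect_equal(v$axis_map, c("Z", "Y", "X"))
  # permuting the grid into anatomical order equals reading an already
  # anatomical volume
  anat <- aperm(v$data, c(3, 2, 1))
  expect_identical(anat, aperm(arr, c(3, 2, 1)))
})
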