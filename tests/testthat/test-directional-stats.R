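# assemble a minimal orientation_field from explicit e1 vectors
toy_field <- function(e1, magnitude = NULL, anisotropy = NULL) {
  n <- nrow(e1)
  if (is.null(magnitude)) magnitude <- rep(1, n)
  if (is.null(anisotropy)) anisotropy <- rep(0.5, n)
  df <- data.frame(cx_um = seq_len(n), cy_um = numeric(n), cz_um = numeric(n),
                   e1x = e1[, 1], e1y = e1[, 2], e1z = e1[, 3],
                   e2x = numeric(n), e2y = numeric(n), e2z = numeric(n),
                   e3x = numeric(n), e3y = numeric(n), e3z = numeric(n),
                   l1_um = magnitude, l2_um = magnitude / 2,
                   l3_um = magnitude / 4,
                   magnitude_um = magnitude,
                   anisotropy_index = anisotropy,
                   material_fraction = rep(0.3, n),
                   i0 = rep(1L, n), j0 = rep(1L, n), k0 = rep(1L, n))
  structure(df, window = window_spec(16L, 16L), source_shape = c(16L, 16L, 16L),
            spacing_um = 1, axis_map = c("X", "Y", "Z"),
            counts = list(tiled = n, retained = n,
                          skipped_low_fraction = 0L, skipped_fit = 0L),
            class = c("orientation_field", "data.frame"))
}

test_that("dominant-axis fractions count largest components with X>Y>Z ties", {
  f <- toy_field(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  s <- dominant_axis_fractions(f)
  expect_equal(unname(s$counts), c(1L, 1L, 1L))
  expect_equal(unname(s$fractions), rep(1 / 3, 3))
  expect_equal(s$total, 3)

  f2 <- toy_field(rbind(c(0.9, 0.1, 0), c(0.8, 0, 0.2)))
  expect_equal(unname(dominant_axis_fractions(f2)$fractions), c(1, 0, 0))

  # exact tie goes to the earlier axis
  f3 <- toy_field(rbind(c(0.7071, 0.7071, 0)))
  expect_equal(dominant_axis(f3), "X")

  expect_error(dominant_axis_fractions(toy_field(matrix(0, 0, 3))), "empty")
})

test_that("plane projection returns the folded in-plane angle and weight", {
  p <- project_to_plane(c(0, 0.6, 0.8), "sagittal_YZ")
  expect_equal(p$angle_deg, 53.13, tolerance = 1e-4)
  expect_equal(p$in_plane_weight, 1)

  p2 <- project_to_plane(c(1, 0, 0), "sagittal_YZ")
  expect_true(is.na(p2$angle_deg))
  expect_lt(p2$in_plane_weight, 1e-6)

  p3 <- project_to_plane(c(0.7071, 0.7071, 0), "transverse_XY")
  expect_equal(p3$angle_deg, 45)

  # axial fold: angles land in [0, 180)
  p4 <- project_to_plane(c(-0.6, 0, -0.8), "frontal_XZ")
  expect_gte(p4$angle_deg, 0)
  expect_lt(p4$angle_deg, 180)
  expect_equal(p4$angle_deg,
               project_to_plane(c(0.6, 0, 0.8), "frontal_XZ")$angle_deg)
})

test_that("rose histograms bin half-open over [0, 180) in both weightings", {
  ang <- c(10, 170) * pi / 180
  e1 <- cbind(cos(ang), sin(ang), 0)
  f <- toy_field(e1, magnitude = c(0.5, 0.7))
  h <- rose_histogram(f, "transverse_XY", 18)
  expect_equal(h$counts[2], 1)    # [10, 20)
  expect_equal(h$counts[18], 1)   # [170, 180)
  expect_equal(sum(h$counts), 2)
  expect_equal(h$sum_magnitude_um[2], 0.5)
  expect_equal(h$sum_magnitude_um[18], 0.7)

  # two samples in one bin accumulate magnitudes
  f2 <- toy_field(rbind(c(1, 0.01, 0), c(1, 0.02, 0)),
                  magnitude = c(0.5, 0.7))
  h2 <- rose_histogram(f2, "transverse_XY", 18)
  expect_equal(max(h2$sum_magnitude_um), 1.2)

  # conservation incl. excluded out-of-plane samples
  f3 <- toy_field(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  h3 <- rose_histogram(f3, "sagittal_YZ", 6)
  expect_equal(sum(h3$counts) + h3$excluded, nrow(f3))
  expect_equal(h3$excluded, 1)

  # frequency and sum-magnitude roses share their support
  expect_equal(which(h3$counts > 0), which(h3$sum_magnitude_um > 0))
})

test_that("anisotropy summaries report mean/median/sd with the n=1 convention", {
  f <- toy_field(matrix(rep(c(1, 0, 0), 3), 3, byrow = TRUE),
                 anisotropy = c(0.2, 0.4, 0.6))
  s <- summarize_anisotropy(f)
  expect_equal(s$mean, 0.4)
  expect_equal(s$median, 0.4)
  expect_equal(s$sd, 0.2)
  expect_equal(s$n, 3)

  s1 <- summarize_anisotropy(toy_field(matrix(c(1, 0, 0), 1),
                                       anisotropy = 0.3))
  expect_equal(s1$sd, 0)

  f2 <- toy_field(rbind(c(1, 0, 0), c(0, 1, 0)), anisotropy = c(0.8, 0.2))
  by_ax <- summarize_anisotropy(f2, by = "axis")
  expect_equal(names(by_ax), c("X", "Y"))
  expect_equal(by_ax$X$mean, 0.8)
  expect_error(summarize_anisotropy(f2, by = "axis", axes = "Z"), "Z")
})

test_that("directional statistics are invariant under axial sign flips", {
  set.seed(8)
  e1 <- t(apply(matrix(rnorm(60), 20, 3), 1, function(v) v / sqrt(sum(v^2))))
  f <- toy_field(e1, magnitude = runif(20, 0.5, 2),
                 anisotropy = runif(20))
  fneg <- f
  fneg[, c("e1x", "e1y", "e1z")] <- -fneg[, c("e1x", "e1y", "e1z")]
  expect_equal(unclass(dominant_axis_fractions(f)),
               unclass(dominant_axis_fractions(fneg)))
  for (pl in c("sagittal_YZ", "frontal_XZ", "transverse_XY")) {
    h1 <- rose_histogram(f, pl, 12)
    h2 <- rose_histogram(fneg, pl, 12)
    expect_equal(h1$counts, h2$counts)
    expect_equal(h1$sum_magnitude_um, h2$sum_magnitude_um)
    expect_equal(h1$excluded, h2$excluded)
  }
})

test_that("rotating the frame 90 degrees about Z swaps X- and Y-dominant counts", {
  set.seed(3)
  base <- rbind(matrix(rep(c(1, 0, 0), 7), ncol = 3, byrow = TRUE),
                matrix(rep(c(0, 1, 0), 4), ncol = 3, byrow = TRUE),
                matrix(rep(c(0, 0, 1), 2), ncol = 3, byrow = TRUE))
  f <- toy_field(base)
  rot <- t(apply(base, 1, function(v) as.numeric(rotmat_z %*% v)))
  frot <- toy_field(rot)
  s <- dominant_axis_fractions(f)
  sr <- dominant_axis_fractions(frot)
  expect_equal(unname(sr$counts[c("Y", "X", "Z")]), unname(s$counts))
})

test_that("region contrast reports per-region summaries and their difference", {
  f <- toy_field(matrix(rep(c(1, 0, 0), 6), 6, byrow = TRUE),
                 anisotropy = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  rc <- region_contrast(f, c(1, 1, 1, 2, 2, 2), 1, 2)
  expect_equal(rc$difference_of_means, 0)

  f2 <- toy_field(matrix(rep(c(1, 0, 0), 4), 4, byrow = TRUE),
                  anisotropy = c(0.8, 0.6, 0.3, 0.1))
  rc2 <- region_contrast(f2, c("rim", "rim", "center", "center"),
                         "rim", "center")
  expect_equal(rc2$difference_of_means, 0.5)
  expect_equal(rc2$summaries$rim$n, 2)
  expect_error(region_contrast(f2, rep("rim", 4), "rim", "center"),
               "center")
})
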