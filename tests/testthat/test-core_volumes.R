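test_that("geometry validates its invariants", {
  expect_error(geometry(c(1, -1, 1), c(4, 4, 4)), "spacing")
  expect_error(geometry(c(1, 1, 1), c(0, 4, 4)), "shape")
  g <- geometry(c(1.06, 1.06, 1.0), c(4, 4, 4))
  expect_equal(g$spacing, c(1.06, 1.06, 1.0))
  expect_equal(voxel_volume_mm3(geometry(c(1.25, 1.25, 1.25), c(2, 2, 2))),
               1.25^3)
})

test_that("NRRD round-trip preserves values bit-exactly and geometry", {
  td <- withr::local_tempdir()
  g <- geometry(c(1.25, 1.25, 1.25), c(4, 4, 4), origin = c(1, 2, 3))
  v <- image_volume(array(5, c(4, 4, 4)), g, "CT")
  write_volume(v, file.path(td, "a.nrrd"))
  r <- read_volume(file.path(td, "a.nrrd"))
  expect_identical(r$values, v$values)
  expect_equal(r$geometry$spacing, g$spacing, tolerance = 1e-12)
  expect_equal(r$geometry$origin, g$origin, tolerance = 1e-12)

  set.seed(1)
  v2 <- image_volume(array(rnorm(64), c(4, 4, 4)), g, "CT")
  write_volume(v2, file.path(td, "b.nrrd"))
  expect_identical(read_volume(file.path(td, "b.nrrd"))$values, v2$values)
})

test_that("NIfTI round-trip preserves values and geometry", {
  td <- withr::local_tempdir()
  g <- geometry(c(1.06, 1.06, 1.0), c(4, 5, 6), origin = c(1, 2, 3))
  set.seed(2)
  v <- image_volume(array(rnorm(120), c(4, 5, 6)), g, "CT")
  write_volume(v, file.path(td, "a.nii.gz"))
  r <- read_volume(file.path(td, "a.nii.gz"))
  expect_equal(r$values, v$values, tolerance = 1e-12)
  expect_equal(r$geometry$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(r$geometry$origin, g$origin, tolerance = 1e-6)
})

test_that("header spacing is taken from the file", {
  td <- withr::local_tempdir()
  g <- geometry(c(1.06, 1.06, 1.0), c(4, 4, 4))
  write_volume(const_volume(0, g), file.path(td, "sp.nrrd"))
  r <- read_volume(file.path(td, "sp.nrrd"))
  expect_equal(r$geometry$spacing, c(1.06, 1.06, 1.0))
})

test_that("malformed volumes are rejected with a named header field", {
  td <- withr::local_tempdir()
  f <- file.path(td, "bad.nrrd")
  writeLines(c("NRRD0004", "type: double", "dimension: 2", "sizes: 4 4",
               "encoding: raw", ""), f)
  expect_error(read_volume(f), "expected 3-D volume")
  f2 <- file.path(td, "bad2.nrrd")
  writeLines(c("NRRD0004", "dimension: 3", "sizes: 2 2 2", "encoding: raw",
               ""), f2)
  expect_error(read_volume(f2), "missing field 'type'")
  expect_error(read_volume(file.path(td, "nope.nrrd")), "not found")
})

test_that("masks round-trip as binary uint8", {
  td <- withr::local_tempdir()
  g <- tiny_geom()
  set.seed(3)
  m <- structure_mask(array(rbinom(64, 1, 0.5), g$shape), g, "brainstem")
  write_volume(m, file.path(td, "m.nrrd"))
  m2 <- read_mask(file.path(td, "m.nrrd"), "brainstem")
  expect_identical(m2$voxels, m$voxels)
  expect_identical(m2$role, "brainstem")
})

test_that("resampling a constant field is exact for any target", {
  v <- const_volume(7, tiny_geom(c(2, 2, 2), c(8, 8, 8)))
  tgt <- geometry(c(1.3, 0.7, 2.1), c(9, 17, 5), origin = c(0.4, 0.2, 0.9))
  out <- resample(v, tgt, "trilinear")
  inside <- out$values != -1000 # fill marks out-of-support voxels
  # trilinear blending of equal corners is exact up to floating point
  expect_lt(max(abs(out$values[inside] - 7)), 1e-12)
})

test_that("trilinear resampling reproduces a linear ramp exactly", {
  g <- geometry(c(2, 2, 2), c(9, 9, 9))
  ramp <- pctqa:::grid_field(g, function(X, Y, Z) X + 0.5 * Y - 0.25 * Z)
  v <- image_volume(ramp, g, "CT")
  tgt <- geometry(c(1, 1, 1), c(15, 15, 15), origin = c(0.5, 0.5, 0.5))
  out <- resample(v, tgt, "trilinear")
  expected <- pctqa:::grid_field(tgt, function(X, Y, Z) X + 0.5 * Y - 0.25 * Z)
  expect_lt(max(abs(out$values - expected)), 1e-9)
  # trilinear output is bounded by the source range
  expect_gte(min(out$values), min(ramp))
  expect_lte(max(out$values), max(ramp))
})

test_that("nearest-neighbour resampling keeps masks binary", {
  g <- tiny_geom(c(1.5, 1.5, 1.5), c(10, 10, 10))
  set.seed(4)
  m <- structure_mask(array(rbinom(1000, 1, 0.3), g$shape), g, "PTV")
  tgt <- geometry(c(1.25, 1.25, 1.25), c(11, 11, 11))
  out <- resample(m, tgt, "nearest")
  expect_true(all(out$voxels %in% c(0L, 1L)))
})

test_that("resampling with no overlap errors", {
  v <- const_volume(1, tiny_geom())
  far <- geometry(c(1, 1, 1), c(4, 4, 4), origin = c(100, 100, 100))
  expect_error(resample(v, far), "overlap")
})

test_that("identity transform returns the input bit-exactly", {
  v <- const_volume(3)
  out <- apply_rigid(v, rigid_transform())
  expect_identical(out, v)
})

test_that("integer-voxel translation shifts a ramp exactly in the interior", {
  g <- geometry(c(1.5, 1.5, 1.5), c(12, 12, 12))
  ramp <- pctqa:::grid_field(g, function(X, Y, Z) 2 * X + Y + 3 * Z)
  v <- image_volume(ramp, g, "CT")
  t <- rigid_transform(translation_mm = c(1.5, 0, 0)) # one voxel in x
  out <- apply_rigid(v, t)
  # output voxel i takes the value of input voxel i-1
  expect_equal(out$values[2:12, , ], ramp[1:11, , ], tolerance = 1e-9)
})

test_that("90-degree rotation permutes an axis-aligned box's extents", {
  g <- geometry(c(1, 1, 1), c(21, 21, 21))
  vox <- array(0L, g$shape)
  vox[9:13, 7:15, 10:12] <- 1L # extents 5 x 9 x 3 around the grid centre
  m <- structure_mask(vox, g, "PTV")
  out <- apply_rigid(m, rigid_transform(rotation_deg = c(0, 0, 90)))
  rng <- function(mm) apply(which(mm$voxels == 1L, arr.ind = TRUE), 2,
                            function(ix) diff(range(ix)) + 1)
  expect_equal(unname(rng(out)), c(9, 5, 3)) # x and y extents swapped
  expect_equal(sum(out$voxels), sum(m$voxels))
})

test_that("transform then inverse recovers the input on the interior", {
  g <- geometry(c(1.5, 1.5, 1.5), c(16, 16, 16))
  smooth <- smooth_field(g, seed = 5, sigma_mm = 5)
  v <- image_volume(smooth + 10, g, "CT")
  t <- rigid_transform(rotation_deg = c(0, 0, 7),
                       translation_mm = c(0.8, -0.4, 0.3))
  back <- apply_rigid(apply_rigid(v, t), t, inverse = TRUE)
  core <- 5:12
  expect_lt(max(abs(back$values[core, core, core] -
                      v$values[core, core, core])), 0.05)
})

test_that("composing a single-axis transform with its inverse is identity", {
  t <- rigid_transform(rotation_deg = c(0, 12, 0),
                       translation_mm = c(3, -2, 1))
  ti <- invert_rigid(t)
  ctr <- c(5, 6, 7)
  f <- pctqa:::rigid_to_affine(t, ctr)
  fi <- pctqa:::rigid_to_affine(ti, ctr)
  comp_R <- fi$R %*% f$R
  comp_off <- fi$R %*% f$offset + fi$offset
  expect_lt(max(abs(comp_R - diag(3))), 1e-9)
  expect_lt(max(abs(comp_off)), 1e-9)
})

test_that("structure volumes convert voxel counts to cm^3", {
  g <- geometry(c(1, 1, 1), c(10, 10, 10))
  expect_equal(structure_volume_cc(full_mask(g)), 1.0)
  g2 <- geometry(c(1.25, 1.25, 1.25), c(2, 2, 2))
  expect_equal(structure_volume_cc(full_mask(g2)), 8 * 1.953125 / 1000)
  empty <- structure_mask(array(0L, g$shape), g, "PTV", allow_empty = TRUE)
  expect_error(structure_volume_cc(empty), "empty")
})

test_that("a voxelised sphere of radius 9.29 mm is close to 3.4 cm^3", {
  g <- geometry(c(0.5, 0.5, 0.5), c(50, 50, 50))
  sph <- pctqa:::in_sphere(g, grid_centre(g), 9.29)
  m <- structure_mask(array(as.integer(sph), g$shape), g, "GTV")
  expect_lt(abs(structure_volume_cc(m) - 3.4) / 3.4, 0.02)
})

test_that("structure volume is additive over disjoint masks", {
  g <- tiny_geom(shape = c(6, 6, 6))
  a <- array(0L, g$shape); a[1:3, , ] <- 1L
  b <- array(0L, g$shape); b[4:6, , ] <- 1L
  ma <- structure_mask(a, g, "A")
  mb <- structure_mask(b, g, "B")
  expect_equal(structure_volume_cc(ma) + structure_volume_cc(mb),
               structure_volume_cc(full_mask(g)))
})

test_that("Euclidean dilation grows a mask by the margin in every direction", {
  g <- geometry(c(1, 1, 1), c(15, 15, 15))
  vox <- array(0L, g$shape); vox[8, 8, 8] <- 1L
  m <- structure_mask(vox, g, "GTV")
  d <- dilate_mask(m, 2)
  idx <- which(d$voxels == 1L, arr.ind = TRUE)
  dist <- sqrt(rowSums((sweep(idx, 2, c(8, 8, 8)))^2))
  expect_true(all(dist <= 2 + 1e-9))
  expect_equal(sum(d$voxels), 33) # voxelised 2 mm ball at 1 mm spacing
  expect_true(all(d$voxels[m$voxels == 1L] == 1L))
})

test_that("manifest round trip restores a full case", {
  td <- withr::local_tempdir()
  case <- generate_case(fast_config(seed = 3, noise_sd = 5))
  mp <- write_case(case, file.path(td, "case"))
  c2 <- read_case_manifest(mp)
  expect_equal(c2$prescription_Gy, case$prescription_Gy)
  expect_equal(c2$ct$values, case$ct$values, tolerance = 1e-12)
  expect_equal(c2$dose_pct$values, case$dose_pct$values, tolerance = 1e-12)
  expect_setequal(names(c2$structures), names(case$structures))
})
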