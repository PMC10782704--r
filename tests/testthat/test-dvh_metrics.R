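make_dose <- function(vals, spacing = 1) {
  n <- length(vals)
  g <- geometry(rep(spacing, 3), c(n, 1, 1))
  image_volume(array(vals, c(n, 1, 1)), g, "dose")
}
make_mask1d <- function(n, spacing = 1, role = "PTV") {
  g <- geometry(rep(spacing, 3), c(n, 1, 1))
  structure_mask(array(1L, c(n, 1, 1)), g, role)
}

test_that("a uniform structure has a step cumulative curve", {
  dvh <- compute_dvh(make_dose(rep(20, 50)), make_mask1d(50))
  cf <- function(d) dvh$cum_frac[max(which(dvh$edges <= d))]
  expect_equal(cf(0), 1)
  expect_equal(cf(19.99), 1)
  expect_equal(cf(20), 1)
  expect_equal(dvh$cum_frac[length(dvh$edges)], 0)
  expect_equal(dvh$dmax, 20)
  expect_equal(dvh$dmin, 20)
})

test_that("two equal-volume voxels at 10 and 20 Gy give fractions 1, 0.5, 0", {
  dvh <- compute_dvh(make_dose(c(10, 20)), make_mask1d(2))
  cf <- function(d) dvh$cum_frac[max(which(dvh$edges <= d))]
  expect_equal(cf(5), 1)
  expect_equal(cf(15), 0.5)
  expect_equal(cf(20.5), 0)
})

test_that("differential bins conserve the structure volume", {
  set.seed(6)
  vals <- runif(500, 0, 25)
  dvh <- compute_dvh(make_dose(vals), make_mask1d(500))
  expect_equal(sum(dvh$diff_cc), structure_volume_cc(make_mask1d(500)),
               tolerance = 1e-9)
  expect_true(all(diff(dvh$cum_frac) <= 1e-15))
  expect_true(all(dvh$diff_cc >= 0))
})

test_that("Dx% is exact for uniform dose and inverts a linear cumulative", {
  uni <- compute_dvh(make_dose(rep(20, 50)), make_mask1d(50))
  expect_equal(dose_at_volume(uni, 50), 20, tolerance = 0.005)
  expect_equal(dose_at_volume(uni, 95), 20, tolerance = 0.005)
  # a linear cumulative from (0 Gy, 1) to (30 Gy, 0) via uniform bin volumes
  lin <- differential_dvh(seq(0.05, 29.95, by = 0.1), rep(1, 300))
  expect_equal(dose_at_volume(lin, 50), 15, tolerance = 0.1)
  expect_error(dose_at_volume(uni, 0), "0, 100")
  expect_error(dose_at_volume(uni, 101), "0, 100")
})

test_that("Dx% is nonincreasing in x", {
  set.seed(7)
  dvh <- compute_dvh(make_dose(runif(400, 5, 30)), make_mask1d(400))
  xs <- c(2, 10, 25, 50, 75, 95, 99)
  ds <- vapply(xs, function(x) dose_at_volume(dvh, x), 0.0)
  expect_true(all(diff(ds) <= 1e-12))
  expect_lte(dose_at_volume(dvh, 95), dose_at_volume(dvh, 50))
})

test_that("absolute-volume dose handles uniform and two-level structures", {
  uni <- compute_dvh(make_dose(rep(20, 50)), make_mask1d(50))
  expect_equal(dose_at_absolute_volume(uni, 0.01), 20, tolerance = 0.005)
  # 1 cm^3 structure, half at 10 Gy and half at 30 Gy: the hottest 0.4 cm^3
  # is all at 30 Gy
  g <- geometry(c(1, 1, 1), c(10, 10, 10))
  v <- array(10, c(10, 10, 10)); v[1:5, , ] <- 30
  dvh <- compute_dvh(image_volume(v, g, "dose"), full_mask(g))
  expect_equal(dose_at_absolute_volume(dvh, 0.4), 30, tolerance = 0.01)
  expect_error(dose_at_absolute_volume(dvh, 1.5), "exceeds")
})

test_that("D0.1cc never exceeds the voxel maximum", {
  set.seed(8)
  dvh <- compute_dvh(make_dose(runif(1000, 0, 40)), make_mask1d(1000))
  expect_lte(dose_at_absolute_volume(dvh, 0.1), dvh$dmax + 0.01)
  # and approaches it as v tends to zero
  expect_equal(dose_at_absolute_volume(dvh, 1e-6), dvh$dmax, tolerance = 0.011)
})

test_that("histogram metrics match direct voxel sorting within one bin", {
  set.seed(9)
  for (rep in 1:5) {
    vals <- runif(2000, 0, 35)
    dvh <- compute_dvh(make_dose(vals), make_mask1d(2000))
    sorted <- sort(vals, decreasing = TRUE)
    for (x in c(10, 50, 95)) {
      brute <- sorted[ceiling(x / 100 * length(vals))]
      expect_lt(abs(dose_at_volume(dvh, x) - brute), 2 * dvh$bin_width)
    }
    brute01 <- sorted[ceiling(0.1 / 1e-3)] # 1 mm^3 voxels = 1e-3 cm^3 each
    expect_lt(abs(dose_at_absolute_volume(dvh, 0.1) - brute01),
              2 * dvh$bin_width)
  }
})

test_that("conformity indices are 1 when dose fills exactly the PTV", {
  g <- geometry(c(1, 1, 1), c(20, 20, 20))
  ptv_vox <- array(0L, g$shape); ptv_vox[8:12, 8:12, 8:12] <- 1L
  ptv <- structure_mask(ptv_vox, g, "PTV")
  dose <- image_volume(array(21 * ptv_vox, g$shape), g, "dose")
  ci <- conformity_indices(dose, ptv, full_mask(g, "body"), 21)
  expect_equal(ci$r100, 1)
  expect_equal(ci$r50, 1)
  empty <- structure_mask(array(0L, g$shape), g, "PTV", allow_empty = TRUE)
  expect_error(conformity_indices(dose, empty, full_mask(g, "body"), 21),
               "empty PTV")
})

test_that("R50 counts the half-prescription shell over the body", {
  g <- geometry(c(1, 1, 1), c(20, 20, 20))
  ptv_vox <- array(0L, g$shape)
  ptv_vox[9:10, 9:10, 9:10] <- 1L # 8 voxels
  ptv <- structure_mask(ptv_vox, g, "PTV")
  dose_arr <- array(0, g$shape)
  dose_arr[ptv_vox == 1L] <- 21
  # shell of exactly twice the PTV volume at half prescription
  shell <- array(0L, g$shape); shell[7:8, 9:10, 9:12] <- 1L # 16 voxels
  dose_arr[shell == 1L] <- 11
  dose <- image_volume(dose_arr, g, "dose")
  ci <- conformity_indices(dose, ptv, full_mask(g, "body"), 21)
  expect_equal(ci$r100, 1)
  expect_equal(ci$r50, 3) # (8 + 16) / 8
})

test_that("D95 renormalisation is a fixed point and a pure scale", {
  g <- geometry(c(1, 1, 1), c(10, 10, 10))
  uni <- image_volume(array(10, g$shape), g, "dose")
  ptv <- full_mask(g)
  out <- normalize_to_d95(uni, ptv, 20)
  expect_equal(attr(out, "scale"), 2, tolerance = 1e-3)
  expect_equal(out$values, uni$values * attr(out, "scale"), tolerance = 1e-12)
  # already-normalised dose is unchanged (scale 1)
  out2 <- normalize_to_d95(out, ptv, 20)
  expect_equal(attr(out2, "scale"), 1, tolerance = 1e-3)
})

test_that("after renormalisation 95% of the PTV is at or above prescription", {
  case <- generate_case(fast_config(seed = 6))
  ptv <- pctqa:::ptv_union(case)
  nd <- normalize_to_d95(case$dose_ct, ptv, case$prescription_Gy)
  dvh <- compute_dvh(nd, ptv)
  expect_equal(dose_at_volume(dvh, 95), case$prescription_Gy,
               tolerance = dvh$bin_width / 2)
})

test_that("DVH metrics scale linearly with a global dose factor", {
  case <- generate_case(fast_config(seed = 8))
  case_scaled <- case
  case_scaled$dose_pct <- perturb_dose(case$dose_ct, scale = 1.01)
  tab <- dvh_metric_table(case_scaled, renormalize_d95 = FALSE)
  oar <- tab[tab$structure != "PTV" & !tab$missing, ]
  # interpolated metrics are quantised by the fixed 0.01 Gy bin grid, so
  # linearity holds to within one bin width (voxel extremes scale exactly)
  expect_lt(max(abs(oar$value_pct - oar$value_ct * 1.01)), 0.011)
  # PTV metrics divided by prescription shift by the same 1%
  ptv <- tab[tab$structure == "PTV" & tab$metric %in%
               c("Dmin/PD", "Dmax/PD", "Dmean/PD"), ]
  expect_equal(ptv$value_pct, ptv$value_ct * 1.01, tolerance = 1e-6)
})

test_that("identical dose pairs give all-zero metric deviations", {
  case <- generate_case(fast_config(seed = 8))
  case$dose_pct <- case$dose_ct
  tab <- dvh_metric_table(case)
  expect_true(all(tab$deviation[!tab$missing] == 0))
})

test_that("a missing structure is flagged, not fatal", {
  case <- generate_case(fast_config(seed = 8))
  case$structures$lens_L <- NULL
  tab <- dvh_metric_table(case)
  expect_true(any(tab$structure == "lens_L" & tab$missing))
  expect_true(all(!tab$missing[tab$structure == "PTV"]))
})
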