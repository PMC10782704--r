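test_that("phantom configuration enforces the study conditions", {
  expect_error(phantom_config(n_lesions = 5), "n_lesions")
  expect_error(phantom_config(lesion_volumes_cc = 0.1), "0.5")
  expect_error(phantom_config(lesion_volumes_cc = 30), "27.3")
  expect_error(phantom_config(fractions = 2, dose_per_fraction_Gy = 10),
               "prescription")
  expect_error(phantom_config(fractions = 1, dose_per_fraction_Gy = 25),
               "prescription")
  expect_silent(phantom_config(fractions = 3, dose_per_fraction_Gy = 7))
  cfg <- phantom_config(fractions = 5, dose_per_fraction_Gy = 6)
  expect_equal(cfg$prescription_Gy, 30)
})

test_that("anatomy produces one GTV per lesion at the requested volume", {
  cfg <- phantom_config(n_lesions = 1, lesion_volumes_cc = 3.4, seed = 2)
  anat <- generate_anatomy(cfg)
  gtvs <- grep("^GTV", names(anat$structures), value = TRUE)
  expect_length(gtvs, 1)
  vol <- structure_volume_cc(anat$structures$GTV_1)
  expect_lt(abs(vol - 3.4) / 3.4, 0.05)
})

test_that("every PTV is strictly larger than its GTV", {
  anat <- generate_anatomy(phantom_config(n_lesions = 2, seed = 5,
                                          lesion_volumes_cc = c(2, 6)))
  for (i in 1:2) {
    g <- anat$structures[[sprintf("GTV_%d", i)]]
    p <- anat$structures[[sprintf("PTV_%d", i)]]
    expect_gt(structure_volume_cc(p), structure_volume_cc(g))
    expect_true(all(p$voxels[g$voxels == 1L] == 1L))
  }
})

test_that("cases are bit-identical under the same seed and differ otherwise", {
  a <- generate_case(fast_config(seed = 11))
  b <- generate_case(fast_config(seed = 11))
  c <- generate_case(fast_config(seed = 12))
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$pct$values, b$pct$values)
  expect_identical(a$dose_ct$values, b$dose_ct$values)
  expect_false(identical(a$ct$values, c$ct$values))
})

test_that("oversized lesions raise a placement error", {
  cfg <- phantom_config(n_lesions = 1, lesion_volumes_cc = 27.3,
                        shape = 32, spacing = 2, seed = 1)
  expect_error(generate_case(cfg), "lesion")
})

test_that("pure offset pCT shifts structure means exactly", {
  cfg <- fast_config(seed = 7, hu_mean_offset = -10, noise_sd = 0,
                     hu_min_smoothing_sigma = 0)
  anat <- generate_anatomy(cfg)
  pct <- generate_pct(anat$ct, anat$structures$body, cfg)
  brain <- anat$structures$brain
  m_ct <- mean(anat$ct$values[brain$voxels == 1L])
  m_pct <- mean(pct$values[brain$voxels == 1L])
  expect_equal(m_ct - m_pct, 10, tolerance = 1e-12)
})

test_that("zero offset, noise and smoothing leaves the pCT identical", {
  cfg <- fast_config(seed = 7, hu_mean_offset = 0, noise_sd = 0,
                     hu_min_smoothing_sigma = 0)
  anat <- generate_anatomy(cfg)
  pct <- generate_pct(anat$ct, anat$structures$body, cfg)
  expect_identical(pct$values, anat$ct$values)
})

test_that("the pCT body outline is identical to the CT", {
  case <- generate_case(fast_config(seed = 9))
  outside <- case$structures$body$voxels == 0L
  expect_identical(case$pct$values[outside], case$ct$values[outside])
})

test_that("smoothing raises the HU minimum inside tissue", {
  cfg <- fast_config(seed = 13, hu_mean_offset = 0, noise_sd = 0,
                     hu_min_smoothing_sigma = 2)
  anat <- generate_anatomy(cfg)
  pct <- generate_pct(anat$ct, anat$structures$body, cfg)
  brain <- anat$structures$brain$voxels == 1L
  expect_gt(min(pct$values[brain]), min(anat$ct$values[brain]))
})

test_that("maximum dose is prescription / 0.8", {
  anat <- generate_anatomy(phantom_config(seed = 2))
  dose <- generate_dose(anat$structures, 21)
  expect_lt(abs(max(dose$values) - 26.25) / 26.25, 0.02)
  expect_equal(dose$geometry$spacing, c(1.25, 1.25, 1.25))
})

test_that("every point inside the PTV receives at least the prescription", {
  anat <- generate_anatomy(phantom_config(seed = 2))
  dose <- generate_dose(anat$structures, 21)
  ptv <- anat$structures$PTV_1
  ctr <- attr(ptv, "centre_mm")
  rad <- attr(ptv, "radius_mm")
  d <- pctqa:::grid_field(dose$geometry, function(X, Y, Z) {
    sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2)
  })
  expect_gte(min(dose$values[d <= rad]), 21 - 1e-9)
})

test_that("dose falls off monotonically with distance from the PTV", {
  anat <- generate_anatomy(phantom_config(seed = 2))
  dose <- generate_dose(anat$structures, 21)
  ctr <- attr(anat$structures$PTV_1, "centre_mm")
  d <- pctqa:::grid_field(dose$geometry, function(X, Y, Z) {
    sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2)
  })
  o <- order(as.vector(d))
  expect_true(all(diff(dose$values[o]) <= 1e-9))
})

test_that("two identical far-apart lesions give a centre-swap-symmetric dose", {
  cfg <- phantom_config(n_lesions = 2, lesion_volumes_cc = c(2, 2), seed = 21)
  anat <- generate_anatomy(cfg)
  c1 <- attr(anat$structures$PTV_1, "centre_mm")
  c2 <- attr(anat$structures$PTV_2, "centre_mm")
  dose <- generate_dose(anat$structures, 21)
  # swap the two centres by swapping the attributes and regenerate
  anat2 <- anat
  attr(anat2$structures$PTV_1, "centre_mm") <- c2
  attr(anat2$structures$PTV_2, "centre_mm") <- c1
  dose2 <- generate_dose(anat2$structures, 21)
  expect_equal(dose$values, dose2$values, tolerance = 1e-12)
})

test_that("perturb_dose scales exactly and identity returns the input", {
  case <- generate_case(fast_config(seed = 3))
  up <- perturb_dose(case$dose_ct, scale = 1.01)
  expect_equal(up$values, case$dose_ct$values * 1.01, tolerance = 1e-12)
  same <- perturb_dose(case$dose_ct, scale = 1)
  expect_identical(same$values, case$dose_ct$values)
})

test_that("a sub-voxel shift changes a linear-gradient dose by shift x gradient", {
  g <- geometry(c(1, 1, 1), c(20, 20, 20))
  grad <- 0.5 # Gy per mm along x
  ramp <- pctqa:::grid_field(g, function(X, Y, Z) 1 + grad * X)
  dose <- image_volume(ramp, g, "dose")
  sh <- perturb_dose(dose, shift = rigid_transform(translation_mm = c(0.5, 0, 0)))
  core <- 5:15
  diff <- dose$values[core, core, core] - sh$values[core, core, core]
  expect_equal(unname(as.vector(diff)), rep(0.5 * grad, length(diff)),
               tolerance = 1e-9)
})

test_that("identically perturbed dose passes gamma at 100% for any criterion", {
  case <- generate_case(fast_config(seed = 3))
  same <- perturb_dose(case$dose_ct, scale = 1)
  for (cr in list(gamma_criteria(1, 1, "local"), gamma_criteria(3, 2, "global"))) {
    res <- gamma_map(case$dose_ct, same, cr)
    expect_equal(res$passing_rate, 100)
    expect_equal(max(res$gamma, na.rm = TRUE), 0)
  }
})

test_that("cohort generation is deterministic and respects its ranges", {
  cases <- generate_cohort(n_cases = 3, seed = 5, shape = 32, spacing = 3,
                           volume_range = c(0.5, 8), with_pct = FALSE)
  cases2 <- generate_cohort(n_cases = 3, seed = 5, shape = 32, spacing = 3,
                            volume_range = c(0.5, 8), with_pct = FALSE)
  expect_identical(vapply(cases, function(x) x$case_id, ""),
                   vapply(cases2, function(x) x$case_id, ""))
  expect_identical(cases[[2]]$dose_pct$values, cases2[[2]]$dose_pct$values)
  for (case in cases) {
    expect_true(case$meta$n_lesions %in% 1:4)
    expect_true(case$fractions %in% c(1, 3, 5))
    expect_true(all(case$meta$lesion_volumes_cc <= 8))
    expect_gt(min(case$dose_ct$values), -1e-12)
  }
})
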