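# Shared fixtures: everything is built in code at test time.

tiny_geom <- function(spacing = c(1, 1, 1), shape = c(4, 4, 4),
                      origin = c(0, 0, 0)) {
  geometry(spacing, shape, origin)
}

const_volume <- function(value = 5, geom = tiny_geom(), modality = "CT") {
  image_volume(array(value, geom$shape), geom, modality)
}

full_mask <- function(geom = tiny_geom(), role = "PTV") {
  structure_mask(array(1L, geom$shape), geom, role)
}

# a fast low-resolution phantom configuration for unit tests
fast_config <- function(seed = 1L, ...) {
  phantom_config(shape = 32, spacing = 3, seed = seed, ...)
}

# smooth random scalar field on a geometry (zero mean), via Gaussian
# smoothing of white noise
smooth_field <- function(geom, seed, sigma_mm = 6) {
  set.seed(seed)
  arr <- array(stats::rnorm(prod(geom$shape)), geom$shape)
  s <- smooth_volume(image_volume(arr, geom, "CT"), sigma_mm)$values
  s - mean(s)
}

# reference/evaluated dose pair on a 20^3 grid with a stereotactic-like
# peak and a realistic pseudo-CT-style deviation (1% scale, sub-mm shift,
# small smooth perturbation)
smooth_dose_pair <- function(seed = 4) {
  g <- geometry(c(2, 2, 2), c(20, 20, 20))
  base <- pctqa:::grid_field(g, function(X, Y, Z) {
    20 * exp(-((X - 19)^2 + (Y - 19)^2 + (Z - 19)^2) / 300)
  })
  ref <- image_volume(base, g, "dose")
  ev <- perturb_dose(ref, scale = 1.01,
                     shift = rigid_transform(translation_mm = c(0.5, -0.3, 0.2)))
  pert <- smooth_field(g, seed) * 0.1 * base / 20
  ev <- image_volume(pmax(ev$values + pert, 0), g, "dose")
  list(ref = ref, ev = ev, geom = g)
}

# independent trilinear interpolation used to cross-check gamma results
r_trilinear <- function(values, geom, points_mm) {
  x <- sweep(points_mm, 2, geom$origin) / matrix(geom$spacing,
                                                 nrow(points_mm), 3,
                                                 byrow = TRUE)
  sh <- geom$shape
  i0 <- pmin(pmax(floor(x), 0), matrix(rep(sh - 2, each = nrow(x)), ncol = 3))
  fr <- x - i0
  out <- numeric(nrow(x))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    out <- out + w * values[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1,
                                  i0[, 3] + dz + 1)]
  }
  out
}
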