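#' Synthetic phantom configuration
#'
#' Defines one paired CT / pseudo-CT head-phantom case with SRT-like dose.
#' Defaults emulate the cohort conditions the pipeline is designed for:
#' 1-4 lesions of 0.5-27.3 cm^3 (median around 3.4 cm^3), prescriptions of
#' 1 x (20-24) Gy, 3 x 7 Gy or 5 x 6 Gy with the prescription at ~80% of the
#' maximum dose, a 1.25 mm isotropic dose grid, and a pseudo-CT whose mean HU
#' sits slightly below the CT with a smoothed (raised) HU minimum.
#'
#' @param n_lesions Number of lesions, 1-4.
#' @param lesion_volumes_cc GTV volumes in cm^3, each in `[0.5, 27.3]`;
#'   recycled to `n_lesions`.
#' @param fractions Number of fractions: 1, 3 or 5.
#' @param dose_per_fraction_Gy Dose per fraction; must match the scheme
#'   (20-24 Gy for 1 fraction, 7 Gy for 3, 6 Gy for 5).
#' @param hu_mean_offset Additive HU offset of the pseudo-CT inside the body
#'   (negative: CT mean above pCT mean). Default -8 HU.
#' @param hu_min_smoothing_sigma Gaussian sigma (mm) of the low-HU floor
#'   raising that emulates the pseudo-CT's smoothed minimum. Default 2 mm.
#' @param noise_sd Additive pseudo-CT noise (HU). Default 10.
#' @param ct_noise_sd CT texture noise inside the body (HU). Default 10.
#' @param falloff_mm Gaussian dose fall-off sigma outside the PTV surface
#'   (mm); 3 mm mimics the rapid stereotactic gradient. Default 3.
#' @param spacing Anatomy grid spacing (mm), scalar or length 3.
#' @param shape Anatomy grid shape (voxels), scalar or length 3.
#' @param dose_scale Multiplicative factor applied to the pseudo-CT dose
#'   (emulates the recalculation deviation). Default 1 (none).
#' @param dose_shift_mm Rigid shift (mm, length 3) applied to the pseudo-CT
#'   dose. Default none.
#' @param dose_noise_sd Additive Gaussian noise (Gy) on the pseudo-CT dose.
#' @param profile Binary label (0/1) carried into the report tables, the
#'   analogue of the planning-MRI sequence type.
#' @param seed Integer seed; the case is fully deterministic given
#'   `(config, seed)`.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_lesions = 1, lesion_volumes_cc = 3.4,
                           fractions = 1, dose_per_fraction_Gy = 21,
                           hu_mean_offset = -8, hu_min_smoothing_sigma = 2,
                           noise_sd = 10, ct_noise_sd = 10, falloff_mm = 3,
                           spacing = 1.5, shape = 64, dose_scale = 1,
                           dose_shift_mm = c(0, 0, 0), dose_noise_sd = 0,
                           profile = 0L, seed = 1L) {
  n_lesions <- as.integer(n_lesions)
  if (n_lesions < 1L || n_lesions > 4L)
    stop("phantom_config: n_lesions must be in 1..4")
  lesion_volumes_cc <- rep_len(as.numeric(lesion_volumes_cc), n_lesions)
  if (any(lesion_volumes_cc < 0.5 - 1e-9) || any(lesion_volumes_cc > 27.3 + 1e-9))
    stop("phantom_config: lesion volumes must be within [0.5, 27.3] cm^3")
  fractions <- as.integer(fractions)
  ok <- switch(as.character(fractions),
               "1" = dose_per_fraction_Gy >= 20 && dose_per_fraction_Gy <= 24,
               "3" = dose_per_fraction_Gy == 7,
               "5" = dose_per_fraction_Gy == 6,
               FALSE)
  if (!isTRUE(ok))
    stop("phantom_config: prescription must be 1 x (20-24) Gy, 3 x 7 Gy or 5 x 6 Gy")
  structure(list(
    n_lesions = n_lesions, lesion_volumes_cc = lesion_volumes_cc,
    fractions = fractions, dose_per_fraction_Gy = dose_per_fraction_Gy,
    prescription_Gy = fractions * dose_per_fraction_Gy,
    hu_mean_offset = hu_mean_offset,
    hu_min_smoothing_sigma = hu_min_smoothing_sigma,
    noise_sd = noise_sd, ct_noise_sd = ct_noise_sd, falloff_mm = falloff_mm,
    spacing = rep_len(as.numeric(spacing), 3),
    shape = rep_len(as.integer(shape), 3),
    dose_scale = dose_scale,
    dose_shift_mm = rep_len(as.numeric(dose_shift_mm), 3),
    dose_noise_sd = dose_noise_sd, profile = as.integer(profile),
    seed = as.integer(seed)), class = "phantom_config")
}

# build full 3-D logical arrays from axis coordinate vectors
grid_field <- function(geom, f) {
  x <- axis_coords(geom, 1); y <- axis_coords(geom, 2); z <- axis_coords(geom, 3)
  X <- array(rep(x, times = length(y) * length(z)), geom$shape)
  Y <- array(rep(rep(y, each = length(x)), times = length(z)), geom$shape)
  Z <- array(rep(z, each = length(x) * length(y)), geom$shape)
  f(X, Y, Z)
}

in_ellipsoid <- function(geom, centre, radii) {
  grid_field(geom, function(X, Y, Z) {
    ((X - centre[1]) / radii[1])^2 + ((Y - centre[2]) / radii[2])^2 +
      ((Z - centre[3]) / radii[3])^2 <= 1
  })
}

in_cylinder_z <- function(geom, centre_xy, radius, z_range) {
  grid_field(geom, function(X, Y, Z) {
    ((X - centre_xy[1])^2 + (Y - centre_xy[2])^2 <= radius^2) &
      Z >= z_range[1] & Z <= z_range[2]
  })
}

in_sphere <- function(geom, centre, radius) {
  grid_field(geom, function(X, Y, Z) {
    (X - centre[1])^2 + (Y - centre[2])^2 + (Z - centre[3])^2 <= radius^2
  })
}

#' Generate the phantom anatomy: CT image and structure masks
#'
#' Head-like phantom: a soft-tissue ellipsoid (~40 HU) inside a bone shell
#' (~1000 HU) inside air (-1000 HU), with OAR masks (brainstem and spinal
#' cord cylinders; small lens / optic-nerve / chiasm ellipsoids) placed at
#' fixed anatomical stations and GTV spheres placed randomly in the brain
#' without overlapping any OAR or each other. Each PTV is its GTV dilated
#' isotropically by 2 mm. Lesion centre and radius are attached to the GTV /
#' PTV masks as attributes `centre_mm` / `radius_mm` (used by the analytic
#' dose model).
#'
#' @param config A [phantom_config()].
#' @return List with `ct` (an [image_volume()]) and `structures` (named list
#'   of [structure_mask()]).
#' @export
generate_anatomy <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  geom <- geometry(config$spacing, config$shape)
  ext <- (geom$shape - 1) * geom$spacing
  h <- min(ext) / 2
  cc <- grid_centre(geom)

  bone_outer <- c(0.92, 0.92, 0.87) * h
  bone_inner <- c(0.82, 0.82, 0.77) * h
  brain_radii <- bone_inner - 3

  body <- in_ellipsoid(geom, cc, bone_outer)
  tissue <- in_ellipsoid(geom, cc, bone_inner)
  brain <- in_ellipsoid(geom, cc, brain_radii)

  oars <- list()
  oars$brainstem <- in_cylinder_z(geom, cc[1:2] + c(0, 0.10 * h),
                                  min(6, 0.13 * h),
                                  cc[3] + c(-0.55, -0.10) * h) & tissue
  oars$spinal_cord <- in_cylinder_z(geom, cc[1:2] + c(0, 0.10 * h),
                                    min(4, 0.08 * h),
                                    cc[3] + c(-0.80, -0.57) * h) & body
  lens_r <- min(3.5, 0.07 * h)
  oars$lens_L <- in_sphere(geom, cc + c(-0.26 * h, -0.64 * h, 0.05 * h), lens_r)
  oars$lens_R <- in_sphere(geom, cc + c(0.26 * h, -0.64 * h, 0.05 * h), lens_r)
  oars$opt_nerve_L <- in_ellipsoid(geom, cc + c(-0.15 * h, -0.38 * h, 0.05 * h),
                                   c(0.05, 0.17, 0.05) * h)
  oars$opt_nerve_R <- in_ellipsoid(geom, cc + c(0.15 * h, -0.38 * h, 0.05 * h),
                                   c(0.05, 0.17, 0.05) * h)
  oars$opt_chiasm <- in_ellipsoid(geom, cc + c(0, -0.20 * h, 0.05 * h),
                                  c(0.12, 0.08, 0.06) * h)

  # physical coordinates of all OAR voxels: exact clearance checks during
  # lesion placement
  oar_union <- Reduce(`|`, oars)
  xs <- axis_coords(geom, 1); ys <- axis_coords(geom, 2); zs <- axis_coords(geom, 3)
  oidx <- which(oar_union, arr.ind = TRUE)
  oar_pts <- cbind(xs[oidx[, 1]], ys[oidx[, 2]], zs[oidx[, 3]])

  min_dist_to_oars <- function(cand) {
    sqrt(min(rowSums((oar_pts - matrix(cand, nrow(oar_pts), 3, byrow = TRUE))^2)))
  }

  # place larger lesions first
  ord <- order(config$lesion_volumes_cc, decreasing = TRUE)
  gtv_r <- (3 * config$lesion_volumes_cc * 1000 / (4 * pi))^(1 / 3)
  centres <- vector("list", config$n_lesions)
  placed <- list()
  for (li in ord) {
    r <- gtv_r[li]
    allowed <- brain_radii - (r + 2) - 1
    if (any(allowed <= 0))
      stop(sprintf("generate_anatomy: lesion %d (%.1f cm^3) does not fit the phantom brain",
                   li, config$lesion_volumes_cc[li]))
    clear_at <- function(cand) {
      if (min_dist_to_oars(cand) < r + 2 + 2) return(FALSE)
      for (p in placed) {
        # PTVs (each GTV + 2 mm) must not touch; 1 mm extra pad
        if (sqrt(sum((cand - p$centre)^2)) < r + p$r + 2 + 2 + 1) return(FALSE)
      }
      TRUE
    }
    cand <- NULL
    for (try in seq_len(1000)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      frac <- stats::runif(1)^(1 / 3)
      cc_try <- cc + u * frac * allowed
      if (clear_at(cc_try)) { cand <- cc_try; break }
    }
    if (is.null(cand)) {
      # deterministic dense sweep: Fibonacci-sphere directions at decreasing
      # radial fractions (the boundary of the allowed region first, where
      # clearance from the central OARs is maximal)
      nf <- 256
      gidx <- seq_len(nf) - 0.5
      phi <- acos(1 - 2 * gidx / nf)
      theta <- pi * (1 + sqrt(5)) * gidx
      dirs <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
      for (frac in seq(1, 0.3, by = -0.1)) {
        for (di in seq_len(nrow(dirs))) {
          cc_try <- cc + dirs[di, ] * frac * allowed
          if (clear_at(cc_try)) { cand <- cc_try; break }
        }
        if (!is.null(cand)) break
      }
    }
    if (is.null(cand))
      stop(sprintf("generate_anatomy: lesion %d (%.1f cm^3) not placeable without overlap",
                   li, config$lesion_volumes_cc[li]))
    placed[[length(placed) + 1]] <- list(centre = cand, r = r)
    centres[[li]] <- cand
  }

  structures <- list()
  gtv_union <- array(FALSE, geom$shape)
  for (li in seq_len(config$n_lesions)) {
    g <- in_sphere(geom, centres[[li]], gtv_r[li])
    gtv_union <- gtv_union | g
    gm <- structure_mask(array(as.integer(g), geom$shape), geom, "GTV")
    attr(gm, "centre_mm") <- centres[[li]]
    attr(gm, "radius_mm") <- gtv_r[li]
    pm <- structure_mask(array(as.integer(in_sphere(geom, centres[[li]],
                                                    gtv_r[li] + 2)),
                               geom$shape), geom, "PTV")
    attr(pm, "centre_mm") <- centres[[li]]
    attr(pm, "radius_mm") <- gtv_r[li] + 2
    structures[[sprintf("GTV_%d", li)]] <- gm
    structures[[sprintf("PTV_%d", li)]] <- pm
  }
  structures$body <- structure_mask(array(as.integer(body), geom$shape),
                                    geom, "body")
  structures$brain <- structure_mask(array(as.integer(brain), geom$shape),
                                     geom, "brain")
  structures$brain_minus_GTV <- structure_mask(
    array(as.integer(brain & !gtv_union), geom$shape), geom, "brain_minus_GTV")
  for (nm in names(oars)) {
    structures[[nm]] <- structure_mask(array(as.integer(oars[[nm]]), geom$shape),
                                       geom, nm)
  }

  base <- array(-1000, geom$shape)
  base[body] <- 1000
  base[tissue] <- 40
  base[gtv_union] <- 60
  noise <- array(0, geom$shape)
  if (config$ct_noise_sd > 0) {
    n_body <- sum(body)
    noise[body] <- stats::rnorm(n_body, 0, config$ct_noise_sd)
  }
  ct <- image_volume(base + noise, geom, "CT")
  list(ct = ct, structures = structures)
}

#' Generate a pseudo-CT from a phantom CT
#'
#' Emulates the deviation structure of a CNN-generated pseudo-CT: a negative
#' mean-HU offset inside the body (CT mean above pCT mean), a raised HU
#' minimum produced by lifting voxels toward a Gaussian-smoothed version of
#' the CT (only noise-scale lifts are applied, so tissue boundaries are
#' preserved), and additive Gaussian noise. The body outline is identical to
#' the CT: air voxels are untouched.
#'
#' @param ct The phantom CT ([image_volume()]).
#' @param body The body [structure_mask()].
#' @param config A [phantom_config()].
#' @return A pseudo-CT [image_volume()].
#' @export
generate_pct <- function(ct, body, config) {
  stopifnot(inherits(ct, "image_volume"), inherits(body, "structure_mask"))
  vals <- ct$values
  inside <- body$voxels == 1L
  lift <- 0
  if (config$hu_min_smoothing_sigma > 0) {
    sm <- smooth_volume(ct, config$hu_min_smoothing_sigma)
    lift <- pmax(0, sm$values - ct$values)
    lift[lift > 50] <- 0 # large differences are tissue boundaries, not noise
  }
  noise <- 0
  if (config$noise_sd > 0) {
    noise <- array(0, dim(vals))
    noise[inside] <- stats::rnorm(sum(inside), 0, config$noise_sd)
  }
  adj <- config$hu_mean_offset + lift + noise
  if (length(adj) > 1) {
    vals[inside] <- vals[inside] + adj[inside]
  } else if (adj != 0) {
    vals[inside] <- vals[inside] + adj
  }
  image_volume(vals, ct$geometry, "pCT")
}

#' Dose grid geometry covering an anatomy extent at 1.25 mm
#' @param geom Anatomy [geometry()].
#' @param spacing Dose grid spacing (mm), default 1.25 isotropic.
#' @return A [geometry()].
#' @export
dose_grid_geometry <- function(geom, spacing = 1.25) {
  ext <- (geom$shape - 1) * geom$spacing
  spacing <- rep_len(spacing, 3)
  geometry(spacing, floor(ext / spacing) + 1, geom$origin)
}

#' Analytic SRT-like dose for the phantom
#'
#' Per lesion, dose is `Dmax * exp(-(d / sigma)^2)` of the distance `d`
#' outside an isodose core placed `delta = sigma * sqrt(ln 1.25)` inside the
#' PTV surface, with `Dmax = prescription / 0.8`. The maximum dose sits at
#' the lesion centre, the prescription isodose falls exactly on the PTV
#' surface (so the prescription is 80% of the maximum and every PTV voxel
#' receives at least the prescription before renormalisation), and the dose
#' decreases monotonically with distance. Multi-lesion doses sum; the grid
#' is 1.25 mm isotropic.
#'
#' @param structures Named structure list containing the `PTV_*` masks.
#' @param prescription_Gy Total prescribed dose (Gy).
#' @param falloff_mm Gaussian fall-off sigma (mm).
#' @param grid Optional dose [geometry()]; default derived from the anatomy
#'   at 1.25 mm.
#' @return A dose [image_volume()].
#' @export
generate_dose <- function(structures, prescription_Gy, falloff_mm = 3,
                          grid = NULL) {
  ptvs <- structures[grepl("^PTV", names(structures))]
  if (length(ptvs) == 0) stop("generate_dose: no PTV masks present")
  ageom <- ptvs[[1]]$geometry
  if (is.null(grid)) grid <- dose_grid_geometry(ageom)
  dmax <- prescription_Gy / 0.8
  # the prescription (80%) isodose sits exactly on the PTV surface
  delta <- falloff_mm * sqrt(log(1.25))
  dose <- array(0, grid$shape)
  for (p in ptvs) {
    ctr <- attr(p, "centre_mm")
    rad <- attr(p, "radius_mm")
    if (!is.null(ctr) && !is.null(rad)) {
      d <- grid_field(grid, function(X, Y, Z) {
        pmax(0, sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2) -
               max(rad - delta, 0))
      })
    } else {
      dv <- cpp_dist_outside(p$voxels, p$geometry$shape, p$geometry$spacing,
                             p$geometry$origin, grid$shape, grid$spacing,
                             grid$origin)
      d <- array(dv, grid$shape) + delta
      inside <- resample(p, grid, "nearest")
      d[inside$voxels == 1L] <- delta
    }
    dose <- dose + dmax * exp(-(d / falloff_mm)^2)
  }
  image_volume(dose, grid, "dose")
}

#' Perturb a dose grid (scale, rigid shift, noise)
#'
#' Creates controlled deviations between the CT dose and the pseudo-CT dose.
#' `scale = 1` with an identity shift and no noise returns the input
#' unchanged.
#'
#' @param dose A dose [image_volume()].
#' @param scale Multiplicative factor.
#' @param shift A [rigid_transform()] (or NULL for identity).
#' @param noise_sd Additive Gaussian noise (Gy), truncated at 0.
#' @param seed Optional seed for the noise draw.
#' @return A dose [image_volume()].
#' @export
perturb_dose <- function(dose, scale = 1, shift = NULL, noise_sd = 0,
                         seed = NULL) {
  stopifnot(inherits(dose, "image_volume"), dose$modality == "dose")
  out <- dose
  if (!is.null(shift) && !is_identity_transform(shift))
    out <- apply_rigid(out, shift, "trilinear")
  vals <- out$values * scale
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- pmax(0, vals + stats::rnorm(length(vals), 0, noise_sd))
  }
  if (identical(scale, 1) && noise_sd == 0 &&
      (is.null(shift) || is_identity_transform(shift))) return(dose)
  image_volume(array(vals, dim(out$values)), out$geometry, "dose")
}

#' Generate one complete phantom case
#'
#' Runs [generate_anatomy()], [generate_pct()], [generate_dose()] and
#' [perturb_dose()] under the case seed and assembles the `phantom_case`
#' container consumed by the metric stages.
#'
#' @param config A [phantom_config()].
#' @param with_pct Generate the pseudo-CT image (disable to save time when
#'   only dose metrics are needed).
#' @return An object of class `phantom_case` with fields `ct`, `pct`,
#'   `dose_ct`, `dose_pct`, `structures`, `prescription_Gy`, `fractions`,
#'   `case_id`, `meta`.
#' @export
generate_case <- function(config, with_pct = TRUE) {
  anat <- generate_anatomy(config)
  pct <- if (with_pct) generate_pct(anat$ct, anat$structures$body, config) else NULL
  dose_ct <- generate_dose(anat$structures, config$prescription_Gy,
                           config$falloff_mm)
  shift <- if (any(config$dose_shift_mm != 0))
    rigid_transform(translation_mm = config$dose_shift_mm) else NULL
  dose_pct <- perturb_dose(dose_ct, config$dose_scale, shift,
                           config$dose_noise_sd, seed = config$seed + 1L)
  structure(list(
    case_id = sprintf("case_%04d", config$seed),
    prescription_Gy = config$prescription_Gy,
    fractions = config$fractions,
    ct = anat$ct, pct = pct, dose_ct = dose_ct, dose_pct = dose_pct,
    structures = anat$structures,
    meta = list(n_lesions = config$n_lesions,
                lesion_volumes_cc = config$lesion_volumes_cc,
                profile = config$profile,
                dose_scale = config$dose_scale,
                dose_shift_mm = config$dose_shift_mm,
                seed = config$seed)), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case %s: %d lesion(s), %d x %g Gy, %d structures\n",
              x$case_id, x$meta$n_lesions, x$fractions,
              x$prescription_Gy / x$fractions, length(x$structures)))
  invisible(x)
}

#' Generate a cohort of phantom cases
#'
#' Case characteristics are drawn to match the emulated cohort: lesion
#' counts with probabilities (25, 4, 4, 1)/34 (or balanced over 1..4),
#' log-normal lesion volumes with median 3.4 cm^3 clipped to
#' `volume_range`, and fractionation 1 / 3 / 5 with probabilities
#' (14, 14, 5)/33. The pseudo-CT dose deviation is a small random scale
#' (s.d. `dose_scale_sd`) plus a random sub-voxel rigid shift; the optional
#' `lesion_effect` plants an additional scale deviation proportional to
#' `(n_lesions - 1)`, used to test planted-effect recovery.
#'
#' @param n_cases Number of cases.
#' @param seed Cohort seed (case seeds are derived from it).
#' @param lesion_counts `"cohort"` (paper-like frequencies) or `"balanced"`.
#' @param dose_scale_sd S.d. of the random dose-scale deviation. Default 0.0015.
#' @param dose_shift_sd_mm S.d. (mm, per axis) of the random rigid shift.
#'   Default 0.2.
#' @param lesion_effect Planted scale deviation per additional lesion.
#'   Default 0 (none); 0.005 is used for recovery tests.
#' @param volume_range Clip range (cm^3) for the drawn lesion volumes;
#'   narrow it when generating on a grid too small to host the largest
#'   lesions.
#' @param with_pct Generate pseudo-CT images (see [generate_case()]).
#' @param ... Further arguments passed to [phantom_config()] (e.g. `shape`,
#'   `spacing`).
#' @return List of `phantom_case` objects.
#' @export
generate_cohort <- function(n_cases = 20, seed = 1L,
                            lesion_counts = c("cohort", "balanced"),
                            dose_scale_sd = 0.0015, dose_shift_sd_mm = 0.2,
                            lesion_effect = 0, with_pct = TRUE,
                            volume_range = c(0.5, 27.3), ...) {
  lesion_counts <- match.arg(lesion_counts)
  set.seed(seed)
  extra <- list(...)
  # the default cohort phantom is larger than the single-case default so that
  # lesions up to 27.3 cm^3 remain placeable
  if (is.null(extra$shape)) extra$shape <- 96
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    nl <- if (lesion_counts == "cohort")
      sample(1:4, 1, prob = c(25, 4, 4, 1)) else ((i - 1) %% 4) + 1
    vols <- pmin(volume_range[2],
                 pmax(volume_range[1], exp(stats::rnorm(nl, log(3.4), 0.7))))
    fx <- sample(c(1, 3, 5), 1, prob = c(14, 14, 5))
    dpf <- switch(as.character(fx), "1" = sample(20:24, 1), "3" = 7, "5" = 6)
    scale <- 1 + stats::rnorm(1, 0, dose_scale_sd) + lesion_effect * (nl - 1)
    shift <- stats::rnorm(3, 0, dose_shift_sd_mm)
    args <- c(list(n_lesions = nl, lesion_volumes_cc = vols, fractions = fx,
                   dose_per_fraction_Gy = dpf, dose_scale = scale,
                   dose_shift_mm = shift, profile = i %% 2,
                   seed = seed * 1000L + i), extra)
    cfg <- do.call(phantom_config, args)
    cases[[i]] <- generate_case(cfg, with_pct = with_pct)
  }
  cases
}
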