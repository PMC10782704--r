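#' Resample a volume onto a target geometry
#'
#' Cross-grid comparisons in this package always resample the *evaluated*
#' volume onto the *reference* geometry. Trilinear output is bounded by the
#' source min/max; masks resampled with `"nearest"` stay binary.
#'
#' @param volume An [image_volume()] or [structure_mask()].
#' @param target Target [geometry()]; must overlap the source extent.
#' @param interpolation `"trilinear"` or `"nearest"`. Masks are always
#'   resampled nearest-neighbour.
#' @param fill Value for target voxels outside the source support
#'   (default 0 Gy for dose, -1000 HU for CT/pCT, 0 for masks).
#' @return Same class as `volume`, on the target geometry. The number of
#'   out-of-support voxels is attached as attribute `n_outside`.
#' @export
resample <- function(volume, target, interpolation = c("trilinear", "nearest"),
                     fill = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(target, "geometry"))
  identity_affine <- diag(4)[1:3, , drop = FALSE]
  if (inherits(volume, "structure_mask")) {
    res <- cpp_resample(as.double(volume$voxels), volume$geometry$shape,
                        volume$geometry$spacing, volume$geometry$origin,
                        target$shape, target$spacing, target$origin,
                        identity_affine, TRUE, if (is.null(fill)) 0 else fill)
    check_overlap(res, target)
    out <- structure_mask(array(as.integer(res$values), dim = target$shape),
                          target, volume$role, allow_empty = TRUE)
    attr(out, "n_outside") <- res$n_outside
    return(out)
  }
  stopifnot(inherits(volume, "image_volume"))
  if (is.null(fill)) fill <- if (volume$modality == "dose") 0 else -1000
  res <- cpp_resample(as.double(volume$values), volume$geometry$shape,
                      volume$geometry$spacing, volume$geometry$origin,
                      target$shape, target$spacing, target$origin,
                      identity_affine, interpolation == "nearest", fill)
  check_overlap(res, target)
  out <- image_volume(array(res$values, dim = target$shape), target,
                      volume$modality)
  attr(out, "n_outside") <- res$n_outside
  out
}

check_overlap <- function(res, target) {
  if (res$n_outside >= prod(target$shape))
    stop("resample: target geometry does not overlap the source extent")
}

#' Apply a rigid transform to a volume
#'
#' The transform maps source physical coordinates to output coordinates:
#' `q = R (p - c) + c + translation`, with rotation centre `c` the grid
#' centre by default. The output stays on the input grid; each output voxel
#' is sampled from the inverse-mapped position in the source. The identity
#' transform returns the input bit-exactly. Out-of-field voxels are filled
#' with 0 Gy / -1000 HU and counted in attribute `n_outside`.
#'
#' @param volume An [image_volume()] or [structure_mask()].
#' @param t A [rigid_transform()].
#' @param interpolation `"trilinear"` or `"nearest"` (masks force nearest).
#' @param centre Rotation centre in mm (default: grid centre).
#' @param fill Out-of-field fill value (defaults as in [resample()]).
#' @param inverse Apply the inverse of `t` instead; `apply_rigid(apply_rigid(x,
#'   t), t, inverse = TRUE)` recovers `x` within interpolation tolerance on
#'   the interior.
#' @return Transformed volume of the same class and geometry.
#' @export
apply_rigid <- function(volume, t, interpolation = c("trilinear", "nearest"),
                        centre = NULL, fill = NULL, inverse = FALSE) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(t, "rigid_transform"))
  geom <- volume$geometry
  if (is_identity_transform(t)) return(volume)
  if (is.null(centre)) centre <- grid_centre(geom)
  fwd <- rigid_to_affine(t, centre)
  if (inverse) {
    # sampling map for the inverse transform is the forward affine itself
    affine <- cbind(fwd$R, fwd$offset)
  } else {
    # inverse map: p = R^T (q - offset)
    Rinv <- t(fwd$R)
    affine <- cbind(Rinv, -Rinv %*% fwd$offset)
  }
  is_mask <- inherits(volume, "structure_mask")
  vals <- if (is_mask) as.double(volume$voxels) else as.double(volume$values)
  if (is.null(fill)) {
    fill <- if (is_mask) 0 else if (volume$modality == "dose") 0 else -1000
  }
  res <- cpp_resample(vals, geom$shape, geom$spacing, geom$origin,
                      geom$shape, geom$spacing, geom$origin, affine,
                      is_mask || interpolation == "nearest", fill)
  if (is_mask) {
    out <- structure_mask(array(as.integer(res$values), dim = geom$shape),
                          geom, volume$role, allow_empty = TRUE)
  } else {
    out <- image_volume(array(pmax(res$values, if (volume$modality == "dose") 0 else -Inf),
                              dim = geom$shape), geom, volume$modality)
  }
  attr(out, "n_outside") <- res$n_outside
  out
}

#' Invert a rigid transform
#'
#' Returns the transform that undoes `t` about the same rotation centre:
#' composing the two yields the identity to better than 1e-9 mm. Because the
#' Euler angles are composed as `Rz Ry Rx`, a closed-form angle triple for
#' the inverse exists only for single-axis rotations; multi-axis inverses
#' should use [apply_rigid()] with `inverse = TRUE` instead.
#'
#' @param t A [rigid_transform()] with at most one nonzero rotation angle.
#' @return A [rigid_transform()].
#' @export
invert_rigid <- function(t) {
  if (sum(t$rotation_deg != 0) > 1)
    stop("invert_rigid: closed-form inverse implemented for <=1 rotation axis; use apply_rigid(..., inverse = TRUE)")
  Rinv <- t(rotation_matrix(t))
  rigid_transform(-t$rotation_deg, as.numeric(-Rinv %*% t$translation_mm))
}

#' Euclidean dilation of a binary mask
#'
#' Adds every voxel whose centre lies within `margin_mm` of a mask voxel
#' centre (distance-transform thresholding rather than a fixed structuring
#' element, so the margin is spacing-independent). Used to grow GTV into PTV
#' with the 2 mm isotropic margin.
#'
#' @param mask A [structure_mask()].
#' @param margin_mm Isotropic margin in mm.
#' @param role Role label for the dilated mask (default: input role).
#' @return A [structure_mask()] on the same geometry.
#' @export
dilate_mask <- function(mask, margin_mm, role = mask$role) {
  stopifnot(inherits(mask, "structure_mask"), margin_mm >= 0)
  if (margin_mm == 0) return(structure_mask(mask$voxels, mask$geometry, role))
  sp <- mask$geometry$spacing
  rad <- floor(margin_mm / sp)
  out <- mask$voxels
  dm <- dim(out)
  for (dk in -rad[3]:rad[3]) for (dj in -rad[2]:rad[2]) for (di in -rad[1]:rad[1]) {
    if (di == 0 && dj == 0 && dk == 0) next
    d2 <- sum((c(di, dj, dk) * sp)^2)
    if (d2 > margin_mm^2 + 1e-12) next
    sh <- shift_array(mask$voxels, c(di, dj, dk))
    out <- out | sh
  }
  structure_mask(array(as.integer(out), dm), mask$geometry, role)
}

# integer shift with zero fill
shift_array <- function(a, d) {
  dm <- dim(a)
  out <- array(0L, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
      dst[[ax]] <- seq_len(dm[ax] + d[ax])
    }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Gaussian smoothing of an image volume
#'
#' Separable Gaussian filter with sigma given in mm (converted to voxel units
#' per axis), truncated at 3 sigma with edge renormalisation.
#'
#' @param volume An [image_volume()].
#' @param sigma_mm Scalar or length-3 sigma in mm; 0 disables.
#' @return Smoothed [image_volume()].
#' @export
smooth_volume <- function(volume, sigma_mm) {
  stopifnot(inherits(volume, "image_volume"))
  sigma_mm <- rep_len(as.numeric(sigma_mm), 3)
  if (all(sigma_mm <= 0)) return(volume)
  sv <- sigma_mm / volume$geometry$spacing
  out <- cpp_smooth3(as.double(volume$values), volume$geometry$shape, sv)
  image_volume(array(out, volume$geometry$shape), volume$geometry,
               volume$modality)
}
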