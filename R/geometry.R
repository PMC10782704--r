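#' Grid geometry of a 3-D volume
#'
#' A geometry ties a voxel grid to physical space: voxel index `(i, j, k)`
#' (1-based) sits at physical position `origin + (index - 1) * spacing`, in
#' millimetres. Voxels are treated as point samples at their centres. The
#' axes are patient-LPS-like but only internal consistency is required: all
#' comparisons in this package are intra-case.
#'
#' @param spacing Numeric length 3, mm per axis; all strictly positive.
#' @param shape Integer length 3, voxel counts per axis; all >= 1.
#' @param origin Numeric length 3, physical position (mm) of voxel (1,1,1).
#' @return An object of class `geometry`.
#' @examples
#' g <- geometry(c(1.25, 1.25, 1.25), c(64, 64, 64))
#' @export
geometry <- function(spacing, shape, origin = c(0, 0, 0)) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  shape <- as.integer(shape)
  stopifnot(length(spacing) == 3, length(origin) == 3, length(shape) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("geometry: spacing must be positive on every axis")
  if (any(is.na(shape)) || any(shape < 1L))
    stop("geometry: shape must be >= 1 on every axis")
  if (any(!is.finite(origin)))
    stop("geometry: origin must be finite")
  structure(list(spacing = spacing, origin = origin, shape = shape),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("geometry: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.geometry <- function(x, ...) {
  sprintf("%dx%dx%d @ (%g,%g,%g) mm", x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

geom_equal <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) && all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Voxel volume in mm^3
#' @param geom A [geometry()].
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume_mm3 <- function(geom) prod(geom$spacing)

#' Physical coordinates of voxel centres along one axis
#' @param geom A [geometry()].
#' @param axis Axis index (1..3).
#' @return Numeric vector of positions in mm.
#' @export
axis_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$shape[axis]) - 1) * geom$spacing[axis]
}

#' 3-D scalar volume with geometry
#'
#' Container for a CT / pseudo-CT image (HU) or a dose grid (Gy). Dose
#' volumes must be nonnegative; HU volumes must be finite.
#'
#' @param values 3-D numeric array matching `geom$shape`.
#' @param geom A [geometry()].
#' @param modality One of `"CT"`, `"pCT"`, `"dose"`.
#' @return An object of class `image_volume` with fields `values`, `geometry`,
#'   `modality`.
#' @export
image_volume <- function(values, geom, modality = c("CT", "pCT", "dose")) {
  modality <- match.arg(modality)
  stopifnot(inherits(geom, "geometry"))
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("image_volume: expected 3-D volume")
  if (!all(dim(values) == geom$shape))
    stop("image_volume: values shape does not match geometry shape")
  storage.mode(values) <- "double"
  if (modality == "dose") {
    if (any(!is.finite(values)) || any(values < 0))
      stop("image_volume: dose values must be finite and >= 0")
  } else {
    if (any(!is.finite(values)))
      stop("image_volume: HU values must be finite")
  }
  structure(list(values = values, geometry = geom, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume [%s] %s, range [%g, %g]\n", x$modality,
              format(x$geometry), min(x$values), max(x$values)))
  invisible(x)
}

#' Binary structure mask
#'
#' @param voxels 3-D array coercible to logical/0-1, matching `geom$shape`.
#' @param geom A [geometry()].
#' @param role Structure role label, e.g. `"PTV"`, `"brainstem"`.
#' @param allow_empty Permit an all-zero mask (default FALSE).
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(voxels, geom, role, allow_empty = FALSE) {
  stopifnot(inherits(geom, "geometry"), is.character(role), length(role) == 1)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("structure_mask: expected 3-D volume")
  if (!all(dim(voxels) == geom$shape))
    stop("structure_mask: voxels shape does not match geometry shape")
  if (!all(voxels %in% c(0, 1, TRUE, FALSE)))
    stop("structure_mask: voxels must be binary")
  storage.mode(voxels) <- "integer"
  if (!allow_empty && sum(voxels) == 0L)
    stop(sprintf("structure_mask: empty structure '%s'", role))
  structure(list(voxels = voxels, geometry = geom, role = role),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s' %s, %d voxels (%.4f cm3)\n", x$role,
              format(x$geometry), sum(x$voxels),
              sum(x$voxels) * voxel_volume_mm3(x$geometry) / 1000))
  invisible(x)
}

#' Structure volume in cm^3
#'
#' Voxel count times voxel volume; the denominator of the R100%/R50%
#' conformity ratios.
#'
#' @param mask A [structure_mask()]; must be nonempty.
#' @return Volume in cm^3.
#' @examples
#' g <- geometry(c(1, 1, 1), c(10, 10, 10))
#' m <- structure_mask(array(1L, c(10, 10, 10)), g, "PTV")
#' structure_volume_cc(m) # 1 cm^3
#' @export
structure_volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  n <- sum(mask$voxels)
  if (n == 0L) stop("structure_volume_cc: empty structure")
  n * voxel_volume_mm3(mask$geometry) / 1000
}

#' Rigid transform (rotation + translation)
#'
#' Rotations are extrinsic, applied about the x, y, z axes in that order
#' (composed as `Rz %*% Ry %*% Rx`) about a centre point chosen at
#' application time; translation follows in mm.
#'
#' @param rotation_deg Numeric length 3, rotation angles in degrees.
#' @param translation_mm Numeric length 3, translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0)) {
  rotation_deg <- as.numeric(rotation_deg)
  translation_mm <- as.numeric(translation_mm)
  stopifnot(length(rotation_deg) == 3, length(translation_mm) == 3)
  if (any(!is.finite(rotation_deg)) || any(!is.finite(translation_mm)))
    stop("rigid_transform: parameters must be finite")
  structure(list(rotation_deg = rotation_deg, translation_mm = translation_mm),
            class = "rigid_transform")
}

rotation_matrix <- function(t) {
  a <- t$rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Inverse of a rigid transform
#'
#' Composing a transform with its inverse is the identity to better than
#' 1e-9 mm.
#'
#' @param t A [rigid_transform()].
#' @return The inverse transform (as rotation matrix + translation, class
#'   `rigid_affine`), suitable for [apply_rigid()].
#' @keywords internal
rigid_to_affine <- function(t, centre) {
  # forward map: q = R (p - c) + c + translation
  R <- rotation_matrix(t)
  offset <- as.numeric(centre - R %*% centre + t$translation_mm)
  list(R = R, offset = offset)
}

#' Physical centre of a volume grid
#' @param geom A [geometry()].
#' @return Numeric length 3 (mm).
#' @export
grid_centre <- function(geom) {
  geom$origin + (geom$shape - 1) * geom$spacing / 2
}

#' Identity test helper for transforms
#' @param t A [rigid_transform()].
#' @return TRUE when rotation and translation are all zero.
#' @export
is_identity_transform <- function(t) {
  all(t$rotation_deg == 0) && all(t$translation_mm == 0)
}
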