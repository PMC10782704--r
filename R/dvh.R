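#' Dose-volume histogram for a structure
#'
#' Builds the differential histogram (absolute cm^3 per uniform dose bin)
#' and the cumulative curve (volume fraction receiving at least each bin
#' edge) of the masked dose values. If the mask geometry differs from the
#' dose grid the mask is resampled nearest-neighbour onto it first.
#'
#' @param dose A dose [image_volume()].
#' @param mask A nonempty [structure_mask()].
#' @param bin_width Dose bin width in Gy (default 0.01).
#' @return An object of class `dvh` with fields `edges`, `diff_cc`,
#'   `cum_frac` (at the edges), `bin_dose` (bin centres), `total_cc`,
#'   `dmax`, `dmin`, `dmean` (voxel extremes / mean), `role`, `bin_width`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.01) {
  stopifnot(inherits(dose, "image_volume"), dose$modality == "dose",
            inherits(mask, "structure_mask"), bin_width > 0)
  if (!geom_equal(dose$geometry, mask$geometry))
    mask <- resample(mask, dose$geometry, "nearest")
  v <- dose$values[mask$voxels == 1L]
  if (length(v) == 0L) stop("compute_dvh: empty mask")
  vox_cc <- voxel_volume_mm3(mask$geometry) / 1000
  nb <- floor(max(v) / bin_width) + 1L
  edges <- seq(0, nb * bin_width, by = bin_width)
  idx <- pmin(floor(v / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  diff_cc <- counts * vox_cc
  total_cc <- length(v) * vox_cc
  # exact: a dose equal to an edge falls in the bin above it, so the
  # suffix-sum of counts is the ">= edge" volume
  cum_frac <- c(rev(cumsum(rev(counts))), 0) / length(v)
  structure(list(edges = edges, diff_cc = diff_cc, cum_frac = cum_frac,
                 bin_dose = edges[-length(edges)] + bin_width / 2,
                 total_cc = total_cc, dmax = max(v), dmin = min(v),
                 dmean = mean(v), role = mask$role, bin_width = bin_width),
            class = "dvh")
}

#' Differential DVH from explicit bins
#'
#' Direct constructor used for radiobiological modelling: arbitrary bin
#' doses with associated volumes (absolute or fractional). A single bin
#' holding the whole volume represents homogeneous irradiation exactly.
#'
#' @param dose_Gy Bin doses (Gy), nonnegative.
#' @param volume Per-bin volumes (any consistent unit), nonnegative, sum > 0.
#' @param role Structure role label.
#' @return An object of class `dvh` (histogram fields derived from the bins).
#' @export
differential_dvh <- function(dose_Gy, volume, role = "structure") {
  stopifnot(length(dose_Gy) == length(volume), all(dose_Gy >= 0),
            all(volume >= 0), sum(volume) > 0)
  o <- order(dose_Gy)
  dose_Gy <- dose_Gy[o]; volume <- volume[o]
  total <- sum(volume)
  # cumulative curve on the exact bin doses
  edges <- c(0, dose_Gy, max(dose_Gy) * 1.000001 + 1e-9)
  cum <- vapply(edges, function(d) sum(volume[dose_Gy >= d]) / total, 0.0)
  w <- if (length(dose_Gy) > 1) min(diff(unique(dose_Gy))) else max(dose_Gy, 1)
  structure(list(edges = edges, diff_cc = volume, cum_frac = cum,
                 bin_dose = dose_Gy, total_cc = total,
                 dmax = max(dose_Gy), dmin = min(dose_Gy),
                 dmean = sum(dose_Gy * volume) / total, role = role,
                 bin_width = w), class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("dvh '%s': %.4f cm^3, dose [%.3f, %.3f] Gy, mean %.3f Gy\n",
              x$role, x$total_cc, x$dmin, x$dmax, x$dmean))
  invisible(x)
}

# largest dose d with cumulative volume >= target, linearly interpolated
# between the bracketing edges
interp_inverse_cum <- function(edges, cumvals, target) {
  if (target > cumvals[1] + 1e-12) return(edges[1])
  i <- max(which(cumvals >= target - 1e-15))
  if (i == length(edges)) return(edges[i])
  c1 <- cumvals[i]; c2 <- cumvals[i + 1]
  if (c2 >= c1) return(edges[i])
  edges[i] + (c1 - target) / (c1 - c2) * (edges[i + 1] - edges[i])
}

#' Dose received by the hottest x% of the structure (Dx%)
#'
#' Linear interpolation on the cumulative curve; nonincreasing in `x`.
#'
#' @param dvh A [compute_dvh()] result.
#' @param x Percentage of the structure volume, in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, x) {
  stopifnot(inherits(dvh, "dvh"))
  if (!is.finite(x) || x <= 0 || x > 100)
    stop("dose_at_volume: x must be in (0, 100]")
  interp_inverse_cum(dvh$edges, dvh$cum_frac, x / 100)
}

#' Dose received by the hottest v cm^3 of the structure (D_v-cc)
#'
#' @param dvh A [compute_dvh()] result (volumes in cm^3).
#' @param v Absolute volume in cm^3, in (0, total volume].
#' @return Dose in Gy; as `v` tends to 0 the value tends to the voxel
#'   maximum (within one bin width).
#' @export
dose_at_absolute_volume <- function(dvh, v) {
  stopifnot(inherits(dvh, "dvh"))
  if (!is.finite(v) || v <= 0) stop("dose_at_absolute_volume: v must be > 0")
  if (v > dvh$total_cc + 1e-12)
    stop("dose_at_absolute_volume: v exceeds the structure volume")
  interp_inverse_cum(dvh$edges, dvh$cum_frac * dvh$total_cc, v)
}

#' Conformity and gradient surrogates R100% and R50%
#'
#' `R100% = Vol(100%) / Vol(PTV)` and `R50% = Vol(50%) / Vol(PTV)`, where
#' Vol(x%) is the *body* volume receiving at least x% of the prescription
#' dose (high-dose overflow and gradient indices).
#'
#' @param dose A dose [image_volume()].
#' @param ptv The PTV [structure_mask()].
#' @param body The body [structure_mask()].
#' @param prescription_Gy Prescription dose (Gy), > 0.
#' @return Named list `r100`, `r50` plus the absolute volumes `vol100_cc`,
#'   `vol50_cc`, `ptv_cc`.
#' @export
conformity_indices <- function(dose, ptv, body, prescription_Gy) {
  stopifnot(prescription_Gy > 0)
  g <- dose$geometry
  if (!geom_equal(ptv$geometry, g)) ptv <- resample(ptv, g, "nearest")
  if (!geom_equal(body$geometry, g)) body <- resample(body, g, "nearest")
  if (sum(ptv$voxels) == 0L) stop("conformity_indices: empty PTV")
  vox_cc <- voxel_volume_mm3(g) / 1000
  inb <- body$voxels == 1L
  vol100 <- sum(dose$values[inb] >= prescription_Gy) * vox_cc
  vol50 <- sum(dose$values[inb] >= prescription_Gy / 2) * vox_cc
  ptv_cc <- sum(ptv$voxels) * vox_cc
  list(r100 = vol100 / ptv_cc, r50 = vol50 / ptv_cc,
       vol100_cc = vol100, vol50_cc = vol50, ptv_cc = ptv_cc)
}

#' Rescale a dose grid so that the PTV's D95% equals the prescription
#'
#' Returns `dose * (prescription / D95%)`; afterwards 95% of the PTV
#' receives at least the prescription dose (to interpolation tolerance).
#'
#' @param dose A dose [image_volume()].
#' @param ptv The PTV [structure_mask()].
#' @param prescription_Gy Prescription dose (Gy).
#' @param bin_width DVH bin width used to measure D95% (Gy).
#' @return The rescaled dose [image_volume()], with the applied scale factor
#'   attached as attribute `scale`.
#' @export
normalize_to_d95 <- function(dose, ptv, prescription_Gy, bin_width = 0.01) {
  dvh <- compute_dvh(dose, ptv, bin_width)
  d95 <- dose_at_volume(dvh, 95)
  if (d95 <= 0) stop("normalize_to_d95: PTV D95% is zero")
  s <- prescription_Gy / d95
  out <- image_volume(dose$values * s, dose$geometry, "dose")
  attr(out, "scale") <- s
  out
}

ptv_union <- function(case) {
  ptvs <- case$structures[grepl("^PTV", names(case$structures))]
  if (length(ptvs) == 0) stop("no PTV masks in case")
  vox <- Reduce(`|`, lapply(ptvs, function(p) p$voxels == 1L))
  structure_mask(array(as.integer(vox), dim(vox)), ptvs[[1]]$geometry, "PTV")
}

gtv_union_mask <- function(case) {
  g <- case$structures[grepl("^GTV", names(case$structures))]
  if (length(g) == 0) return(NULL)
  vox <- Reduce(`|`, lapply(g, function(p) p$voxels == 1L))
  structure_mask(array(as.integer(vox), dim(vox)), g[[1]]$geometry, "GTV")
}

#' DVH metric table for one case
#'
#' Computes the standard metric panel for both dose grids: PTV
#' Dmin/Dmax/Dmean divided by the prescription, R100% and R50%; serial OARs
#' (lenses, optic nerves, chiasm, brainstem, spinal cord) Dmax and D0.1cc in
#' Gy; normal brain (brain minus GTV) D50%. PTV metrics are taken from the
#' (optionally) D95-renormalised dose; OAR metrics are not renormalised.
#'
#' @param case A `phantom_case`.
#' @param bin_width DVH bin width (Gy).
#' @param renormalize_d95 Rescale each dose grid so PTV D95% equals the
#'   prescription before extracting PTV metrics (default TRUE).
#' @return Long data.frame: `case_id`, `structure`, `metric`, `value_ct`,
#'   `value_pct`, `deviation` (CT minus pCT), `abs_deviation`, `missing`.
#' @export
dvh_metric_table <- function(case, bin_width = 0.01, renormalize_d95 = TRUE) {
  stopifnot(inherits(case, "phantom_case"))
  pd <- case$prescription_Gy
  ptv <- ptv_union(case)
  body <- case$structures$body
  doses <- list(ct = case$dose_ct, pct = case$dose_pct)
  ptv_doses <- doses
  if (renormalize_d95)
    ptv_doses <- lapply(doses, normalize_to_d95, ptv = ptv,
                        prescription_Gy = pd, bin_width = bin_width)

  rows <- list()
  add <- function(structure, metric, vals, missing = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      case_id = case$case_id, structure = structure, metric = metric,
      value_ct = vals[1], value_pct = vals[2],
      deviation = vals[1] - vals[2], abs_deviation = abs(vals[1] - vals[2]),
      missing = missing, stringsAsFactors = FALSE)
  }

  ptv_dvh <- lapply(ptv_doses, compute_dvh, mask = ptv, bin_width = bin_width)
  add("PTV", "Dmin/PD", vapply(ptv_dvh, function(d) d$dmin / pd, 0.0))
  add("PTV", "Dmax/PD", vapply(ptv_dvh, function(d) d$dmax / pd, 0.0))
  add("PTV", "Dmean/PD", vapply(ptv_dvh, function(d) d$dmean / pd, 0.0))
  if (!is.null(body)) {
    ci <- lapply(ptv_doses, conformity_indices, ptv = ptv, body = body,
                 prescription_Gy = pd)
    add("PTV", "R100%", vapply(ci, function(x) x$r100, 0.0))
    add("PTV", "R50%", vapply(ci, function(x) x$r50, 0.0))
  }

  serial <- c("lens_L", "lens_R", "opt_chiasm", "opt_nerve_L", "opt_nerve_R",
              "spinal_cord", "brainstem")
  for (s in serial) {
    m <- case$structures[[s]]
    if (is.null(m)) {
      add(s, "Dmax", c(NA_real_, NA_real_), missing = TRUE)
      next
    }
    dv <- lapply(doses, compute_dvh, mask = m, bin_width = bin_width)
    add(s, "Dmax", vapply(dv, function(d) d$dmax, 0.0))
    v01 <- vapply(dv, function(d)
      dose_at_absolute_volume(d, min(0.1, d$total_cc)), 0.0)
    add(s, "D0.1cc", v01)
  }
  bm <- case$structures$brain_minus_GTV
  if (!is.null(bm)) {
    dv <- lapply(doses, compute_dvh, mask = bm, bin_width = bin_width)
    add("brain_minus_GTV", "D50%", vapply(dv, dose_at_volume, x = 50, 0.0))
  } else {
    add("brain_minus_GTV", "D50%", c(NA_real_, NA_real_), missing = TRUE)
  }
  do.call(rbind, rows)
}
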