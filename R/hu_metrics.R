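#' Per-structure HU summary statistics
#'
#' Maximum, minimum, mean and standard deviation of the HU values inside a
#' structure, plus the structure volume. The standard deviation uses the
#' population formula (divisor N). Structures below `min_voxels` are flagged
#' `unreliable` (the small-lens caveat: statistics on a handful of voxels
#' are dominated by sampling).
#'
#' @param volume An [image_volume()] (CT or pCT).
#' @param mask A nonempty [structure_mask()] on the same geometry.
#' @param min_voxels Voxel-count floor below which the result is flagged.
#' @return A one-row data.frame of class `hu_stats`: `role`, `max`, `min`,
#'   `mean`, `sd`, `volume_cc`, `n_voxels`, `unreliable`.
#' @export
hu_summary <- function(volume, mask, min_voxels = 5L) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "structure_mask"))
  if (!geom_equal(volume$geometry, mask$geometry))
    stop("hu_summary: volume and mask geometries differ; resample first")
  v <- volume$values[mask$voxels == 1L]
  n <- length(v)
  if (n == 0L) stop("hu_summary: empty mask")
  m <- mean(v)
  out <- data.frame(role = mask$role, max = max(v), min = min(v), mean = m,
                    sd = sqrt(mean((v - m)^2)),
                    volume_cc = n * voxel_volume_mm3(mask$geometry) / 1000,
                    n_voxels = n, unreliable = n < min_voxels,
                    stringsAsFactors = FALSE)
  class(out) <- c("hu_stats", class(out))
  out
}

#' Signed and absolute deviations between two HU summaries
#'
#' @param a,b `hu_stats` rows for the same structure role (conventionally
#'   `a` = planning CT, `b` = pseudo-CT, so a positive mean deviation means
#'   the CT mean is higher).
#' @return A one-row data.frame with signed (`d_*`) and absolute (`ad_*`)
#'   deviations for max, min, mean, sd and volume.
#' @export
hu_deviation <- function(a, b) {
  stopifnot(inherits(a, "hu_stats"), inherits(b, "hu_stats"))
  if (!identical(a$role, b$role))
    stop(sprintf("hu_deviation: role mismatch ('%s' vs '%s')", a$role, b$role))
  fields <- c("max", "min", "mean", "sd", "volume_cc")
  out <- data.frame(role = a$role, stringsAsFactors = FALSE)
  for (f in fields) {
    d <- a[[f]] - b[[f]]
    out[[paste0("d_", f)]] <- d
    out[[paste0("ad_", f)]] <- abs(d)
  }
  out$unreliable <- a$unreliable | b$unreliable
  out
}

#' Tidy HU comparison table for a case
#'
#' One row per (structure, image, statistic): the long-format CSV-ready HU
#' comparison across CT and pseudo-CT for all structures of a case.
#'
#' @param case A `phantom_case` (or manifest-loaded case).
#' @param roles Structure names to include; default all except GTV/PTV
#'   helpers `body`.
#' @return A data.frame with columns `case_id`, `structure`, `image`,
#'   `statistic`, `value`.
#' @export
hu_table <- function(case, roles = NULL) {
  stopifnot(inherits(case, "phantom_case"))
  if (is.null(case$pct)) stop("hu_table: case has no pseudo-CT image")
  if (is.null(roles)) {
    roles <- setdiff(names(case$structures), c("body", "brain"))
    roles <- roles[!grepl("^GTV", roles)]
  }
  rows <- list()
  for (r in roles) {
    m <- case$structures[[r]]
    for (img in c("CT", "pCT")) {
      vol <- if (img == "CT") case$ct else case$pct
      s <- hu_summary(vol, m)
      for (f in c("max", "min", "mean", "sd", "volume_cc")) {
        rows[[length(rows) + 1]] <- data.frame(
          case_id = case$case_id, structure = r, image = img, statistic = f,
          value = s[[f]], unreliable = s$unreliable, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
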