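#' Read a 3-D volume from NRRD or NIfTI
#'
#' Geometry is populated from the file header; values are returned unscaled
#' beyond the header's slope/intercept. Only 3-D scalar data are accepted.
#'
#' @param path File path; format inferred from the extension when `format`
#'   is `"auto"` (`.nrrd` / `.nhdr` vs `.nii` / `.nii.gz`).
#' @param format `"auto"`, `"NRRD"` or `"NIfTI"`.
#' @param modality Modality tag for the returned volume.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "NRRD", "NIfTI"),
                        modality = "CT") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("read_volume: file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) "NRRD"
              else "NIfTI"
  }
  if (format == "NRRD") read_nrrd(path, modality) else read_nifti(path, modality)
}

#' Write a 3-D volume to NRRD or NIfTI
#'
#' @param vol An [image_volume()] or [structure_mask()]. Masks are written as
#'   uint8 0/1 grids; images as doubles.
#' @param path Destination path.
#' @param format `"auto"`, `"NRRD"` or `"NIfTI"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "NRRD", "NIfTI")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) "NRRD"
              else "NIfTI"
  }
  is_mask <- inherits(vol, "structure_mask")
  values <- if (is_mask) vol$voxels else vol$values
  geom <- vol$geometry
  if (format == "NRRD") {
    write_nrrd(values, geom, path, uint8 = is_mask)
  } else {
    write_nifti_vol(values, geom, path, uint8 = is_mask)
  }
  invisible(path)
}

#' Read a structure mask from file
#' @inheritParams read_volume
#' @param role Structure role label.
#' @param allow_empty Permit an all-zero mask.
#' @return A [structure_mask()].
#' @export
read_mask <- function(path, role, format = c("auto", "NRRD", "NIfTI"),
                      allow_empty = FALSE) {
  v <- read_volume(path, match.arg(format), modality = "CT")
  vox <- v$values
  if (!all(vox %in% c(0, 1)))
    stop("read_mask: file does not contain a binary mask")
  structure_mask(vox, v$geometry, role, allow_empty = allow_empty)
}

nrrd_type_map <- list(
  "double" = list(what = "double", size = 8, signed = TRUE),
  "float"  = list(what = "double", size = 4, signed = TRUE),
  "short"  = list(what = "integer", size = 2, signed = TRUE),
  "signed short" = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "int"    = list(what = "integer", size = 4, signed = TRUE),
  "signed int" = list(what = "integer", size = 4, signed = TRUE),
  "uchar"  = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8"  = list(what = "integer", size = 1, signed = FALSE),
  "uint8_t" = list(what = "integer", size = 1, signed = FALSE)
)

read_nrrd <- function(path, modality) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop("read_volume: not an NRRD file (bad magic line)")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("read_volume: NRRD header ended without blank separator line")
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(m) != 3)
      stop(sprintf("read_volume: malformed NRRD header line: '%s'", line))
    fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- function(f) {
    if (is.null(fields[[f]]))
      stop(sprintf("read_volume: NRRD header missing field '%s'", f))
    fields[[f]]
  }
  dimension <- as.integer(need("dimension"))
  if (dimension != 3L)
    stop("read_volume: expected 3-D volume (header field 'dimension')")
  sizes <- as.integer(strsplit(need("sizes"), "[[:space:]]+")[[1]])
  if (length(sizes) != 3L || any(is.na(sizes)))
    stop("read_volume: malformed NRRD header field 'sizes'")
  typ <- nrrd_type_map[[tolower(need("type"))]]
  if (is.null(typ))
    stop(sprintf("read_volume: unsupported NRRD type '%s'", fields$type))
  encoding <- tolower(need("encoding"))
  if (!encoding %in% c("raw"))
    stop(sprintf("read_volume: unsupported NRRD encoding '%s'", encoding))
  endian <- if (!is.null(fields$endian)) fields$endian else "little"
  # geometry: prefer space directions (axis-aligned only), else spacings
  spacing <- NULL
  if (!is.null(fields[["space directions"]])) {
    vecs <- parse_nrrd_vectors(fields[["space directions"]])
    if (length(vecs) != 3)
      stop("read_volume: malformed NRRD header field 'space directions'")
    spacing <- numeric(3)
    for (a in 1:3) {
      v <- vecs[[a]]
      if (sum(v != 0) != 1 || v[a] <= 0)
        stop("read_volume: only axis-aligned 'space directions' are supported")
      spacing[a] <- v[a]
    }
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "[[:space:]]+")[[1]])
  } else {
    stop("read_volume: NRRD header missing field 'space directions'/'spacings'")
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  n <- prod(sizes)
  raw_vals <- readBin(con, what = typ$what, n = n, size = typ$size,
                      signed = if (typ$size >= 4) TRUE else typ$signed,
                      endian = endian)
  if (length(raw_vals) != n)
    stop("read_volume: NRRD data block shorter than 'sizes' promises")
  arr <- array(as.double(raw_vals), dim = sizes)
  image_volume(arr, geometry(spacing, sizes, origin), modality)
}

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v) {
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
  })
}

write_nrrd <- function(values, geom, path, uint8 = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (uint8) "uchar" else "double"),
    "dimension: 3",
    sprintf("sizes: %d %d %d", geom$shape[1], geom$shape[2], geom$shape[3]),
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            geom$spacing[1], geom$spacing[2], geom$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            geom$origin[1], geom$origin[2], geom$origin[3]),
    "endian: little",
    "encoding: raw",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  if (uint8) {
    writeBin(as.raw(as.integer(values)), con)
  } else {
    writeBin(as.double(values), con, size = 8, endian = "little")
  }
}

read_nifti <- function(path, modality) {
  img <- RNifti::readNifti(path, internal = FALSE)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("read_volume: expected 3-D volume")
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf)) origin <- xf[1:3, 4]
  image_volume(array(as.double(arr), dim = dim(arr)),
               geometry(spacing, dim(arr), origin), modality)
}

write_nifti_vol <- function(values, geom, path, uint8 = FALSE) {
  arr <- array(as.double(values), dim = geom$shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geom$spacing
  mat <- diag(4)
  diag(mat)[1:3] <- geom$spacing
  mat[1:3, 4] <- geom$origin
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  img <- RNifti::`qform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path, datatype = if (uint8) "uint8" else "double")
  invisible(path)
}

#' Read a case manifest
#'
#' A case manifest is a JSON file with fields `case_id`, `prescription_Gy`,
#' `fractions`, `volumes` (named paths: `ct`, `pct`, `dose_ct`, `dose_pct`)
#' and `structures` (role -> path). Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path Path to the manifest JSON.
#' @return A list with the loaded volumes and masks (a `phantom_case`-shaped
#'   list usable by [dvh_metric_table()] and friends).
#' @export
read_case_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("case_id", "prescription_Gy", "fractions", "volumes", "structures"))
    if (is.null(man[[f]]))
      stop(sprintf("read_case_manifest: missing field '%s'", f))
  base <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  vols <- lapply(seq_along(man$volumes), function(i) {
    nm <- names(man$volumes)[i]
    mod <- switch(nm, ct = "CT", pct = "pCT", "dose")
    read_volume(rel(man$volumes[[i]]), modality = mod)
  })
  names(vols) <- names(man$volumes)
  structs <- lapply(seq_along(man$structures), function(i) {
    read_mask(rel(man$structures[[i]]), role = names(man$structures)[i])
  })
  names(structs) <- names(man$structures)
  structure(list(case_id = man$case_id,
                 prescription_Gy = man$prescription_Gy,
                 fractions = man$fractions,
                 ct = vols$ct, pct = vols$pct,
                 dose_ct = vols$dose_ct, dose_pct = vols$dose_pct,
                 structures = structs,
                 meta = man$meta),
            class = "phantom_case")
}

#' Write a phantom case to disk as NRRD volumes plus a JSON manifest
#'
#' @param case A `phantom_case` (see [generate_case()]).
#' @param dir Output directory (created if missing).
#' @return Path of the written manifest, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vols <- c("ct", "pct", "dose_ct", "dose_pct")
  paths <- list()
  for (v in vols) {
    p <- sprintf("%s.nrrd", v)
    write_volume(case[[v]], file.path(dir, p))
    paths[[v]] <- p
  }
  spaths <- list()
  for (r in names(case$structures)) {
    p <- sprintf("struct_%s.nrrd", r)
    write_volume(case$structures[[r]], file.path(dir, p))
    spaths[[r]] <- p
  }
  man <- list(case_id = case$case_id,
              prescription_Gy = case$prescription_Gy,
              fractions = case$fractions,
              volumes = paths, structures = spaths, meta = case$meta)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}
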