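#' Bone volume container
#'
#' A `bone_volume` is a binary 3D voxel grid with isotropic physical spacing,
#' an origin, and optional landmarks and per-individual metadata.  Voxel
#' `[i, j, k]` has its center at physical coordinates
#' `origin + (c(i, j, k) - 0.5) * voxel_mm` (x along the first array
#' dimension, y along the second, z along the third; z increases
#' proximal-to-distal once aligned).
#'
#' @param mask logical or 0/1 3D array of bone voxels.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param origin physical coordinates (mm) of the corner of voxel `[1, 1, 1]`.
#' @param landmarks optional list with 3-vectors `proximal`, `distal` and
#'   `roll_ref`, all in physical mm coordinates.
#' @param meta named list of per-individual metadata (group, sex, side,
#'   mass_kg, ...).
#' @param truth optional list of analytic ground-truth fields (used by
#'   phantoms): `thickness` and `sma`, each a 17 x 360 matrix, plus
#'   `fractions` and `angles_deg`.
#' @return an object of class `bone_volume`.
#' @export
bone_volume <- function(mask, voxel_mm, origin = c(0, 0, 0),
                        landmarks = NULL, meta = list(), truth = NULL) {
  stopifnot(length(dim(mask)) == 3, is.numeric(voxel_mm), voxel_mm > 0,
            length(origin) == 3)
  storage.mode(mask) <- "logical"
  if (!is.null(landmarks)) validate_landmarks(landmarks)
  structure(
    list(mask = mask, voxel_mm = voxel_mm, origin = as.numeric(origin),
         landmarks = landmarks, meta = meta, truth = truth),
    class = "bone_volume")
}

validate_landmarks <- function(lm) {
  need <- c("proximal", "distal")
  if (!all(need %in% names(lm)))
    stop("landmarks must contain 'proximal' and 'distal' points")
  for (nm in intersect(c(need, "roll_ref"), names(lm)))
    stopifnot(is.numeric(lm[[nm]]), length(lm[[nm]]) == 3)
  if (sqrt(sum((lm$proximal - lm$distal)^2)) <= .Machine$double.eps^0.5)
    stop("proximal and distal landmarks coincide")
  invisible(lm)
}

#' @export
print.bone_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<bone_volume> %d x %d x %d voxels @ %.3g mm (%.0f bone voxels)\n",
              d[1], d[2], d[3], x$voxel_mm, sum(x$mask)))
  if (!is.null(x$landmarks))
    cat(sprintf("  landmark axis length %.2f mm\n",
                sqrt(sum((x$landmarks$distal - x$landmarks$proximal)^2))))
  invisible(x)
}

#' Physical coordinates of voxel centers along one axis
#' @noRd
axis_coords <- function(vol, axis) {
  n <- dim(vol$mask)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel_mm
}

#' Write a volume as a multi-page TIFF stack plus plain-text sidecar
#'
#' One TIFF page per z slice (x along image rows).  The sidecar
#' (`<path>.meta.txt`) stores `key: value` lines with spacing, origin,
#' landmarks (mm, `x y z` order) and any scalar metadata, so the pair round
#' trips through [read_volume_tiff()].
#'
#' @param vol a [bone_volume()].
#' @param path output TIFF path; the sidecar gets `.meta.txt` appended.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  pages <- lapply(seq_len(dim(vol$mask)[3]),
                  function(k) {
                    m <- vol$mask[, , k] * 1.0
                    storage.mode(m) <- "double"
                    m
                  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- c(
    list(voxel_mm = vol$voxel_mm,
         origin = paste(vol$origin, collapse = " "),
         dim = paste(dim(vol$mask), collapse = " ")),
    if (!is.null(vol$landmarks))
      lapply(vol$landmarks, function(p) paste(p, collapse = " ")),
    vol$meta[vapply(vol$meta, function(v) is.atomic(v) && length(v) == 1,
                    logical(1))])
  writeLines(sprintf("%s: %s", names(meta), unlist(lapply(meta, as.character))),
             paste0(path, ".meta.txt"))
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#' @param path TIFF path with `<path>.meta.txt` sidecar alongside.
#' @return a [bone_volume()] (without truth fields).
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  kv <- read_keyvalue(paste0(path, ".meta.txt"))
  num3 <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  d <- as.integer(num3(kv$dim))
  mask <- array(FALSE, d)
  for (k in seq_len(d[3])) mask[, , k] <- pages[[k]] > 0.5
  lm <- NULL
  if (!is.null(kv$proximal))
    lm <- list(proximal = num3(kv$proximal), distal = num3(kv$distal),
               roll_ref = if (!is.null(kv$roll_ref)) num3(kv$roll_ref))
  meta <- kv[setdiff(names(kv),
                     c("voxel_mm", "origin", "dim", "proximal", "distal",
                       "roll_ref"))]
  meta <- lapply(meta, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  bone_volume(mask, as.numeric(kv$voxel_mm), num3(kv$origin),
              landmarks = lm, meta = meta)
}

read_keyvalue <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)
  out <- lapply(kv, function(p) trimws(p[2]))
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}

#' Read landmark coordinates from a plain-text file
#'
#' Expects three whitespace-separated `x y z` physical mm coordinates per
#' line, in the order proximal center, distal center, roll reference.  Axis
#' order is x, y, z matching the first, second and third array dimensions of
#' the volume; coordinates are measured from the volume origin (not voxel
#' indices).
#'
#' @param path text file path.
#' @return landmark list as used by [bone_volume()].
#' @export
read_landmarks <- function(path) {
  rows <- utils::read.table(path, col.names = c("x", "y", "z"))
  if (nrow(rows) < 2) stop("landmark file needs at least proximal and distal points")
  lm <- list(proximal = as.numeric(rows[1, ]), distal = as.numeric(rows[2, ]))
  if (nrow(rows) >= 3) lm$roll_ref <- as.numeric(rows[3, ])
  validate_landmarks(lm)
  lm
}
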