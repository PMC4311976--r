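#' Standardization of structural properties
#'
#' Cortical thickness is standardized by mechanical length (dimensionless
#' sCBT = t / L); second moments of area by the product of body mass and
#' length (sSMA = I / (M * L), mm^3/kg).
#'
#' @param thickness thickness values (mm; vector or matrix).
#' @param length_mm mechanical length (mm, > 0).
#' @return standardized values with the shape of the input.
#' @export
standardize_cbt <- function(thickness, length_mm) {
  stopifnot(is.numeric(length_mm), length_mm > 0)
  thickness / length_mm
}

#' @rdname standardize_cbt
#' @param sma SMA values (mm^4; vector or matrix).
#' @param mass_kg body mass (kg, > 0).
#' @export
standardize_sma <- function(sma, mass_kg, length_mm) {
  stopifnot(is.numeric(mass_kg), mass_kg > 0,
            is.numeric(length_mm), length_mm > 0)
  sma / (mass_kg * length_mm)
}

#' Body mass used for standardization
#'
#' `body_mass_estimate()` resolves one individual's mass: either a direct
#' mass, or a femoral-head-diameter path through user-supplied sex-specific
#' linear regression coefficients (`mass = a + b * diameter`).
#' `standardization_mass()` then replaces individual masses by group- and
#' sex-specific means, the convention used when standardizing properties.
#'
#' @param meta list or one-row data.frame with `mass_kg`, or
#'   `femoral_head_mm` plus `sex`.
#' @param coef named list of sex-specific coefficients,
#'   e.g. `list(M = c(a = , b = ), F = c(a = , b = ))`; required for the
#'   diameter path.
#' @return mass in kg.
#' @export
body_mass_estimate <- function(meta, coef = NULL) {
  if (!is.null(meta$mass_kg) && is.finite(meta$mass_kg))
    return(as.numeric(meta$mass_kg))
  if (is.null(meta$femoral_head_mm))
    stop("need either mass_kg or femoral_head_mm in metadata")
  if (is.null(coef) || is.null(coef[[meta$sex]]))
    stop("femoral head diameter path requires sex-specific regression coefficients")
  cf <- coef[[meta$sex]]
  as.numeric(cf["a"] + cf["b"] * meta$femoral_head_mm)
}

#' @rdname body_mass_estimate
#' @param metadata data.frame with columns `group`, `sex` and `mass_kg`
#'   (individual masses, possibly from [body_mass_estimate()]).
#' @param by grouping columns for the means (default group and sex).
#' @return numeric vector: for each row of `metadata`, the group/sex mean
#'   mass to use in standardization.
#' @export
standardization_mass <- function(metadata, by = c("group", "sex")) {
  key <- interaction(metadata[by], drop = TRUE)
  means <- tapply(metadata$mass_kg, key, mean)
  as.numeric(means[as.character(key)])
}

#' Morphometric map of one individual
#'
#' Assembles the standardized 17 x 360 matrix (rows = sections proximal to
#' distal, columns = degrees counter-clockwise from the reference
#' direction) for one property.
#'
#' @param profiles a `bone_profiles` object from [measure_rendering()].
#' @param property `"CBT"` or `"SMA"`.
#' @param mass_kg body mass for SMA standardization (kg).
#' @param id,group identifiers attached as attributes.
#' @return a `morphometric_map`: 17 x 360 numeric matrix with attributes
#'   `property`, `id`, `group`.
#' @export
morphometric_map <- function(profiles, property = c("CBT", "SMA"),
                             mass_kg = NULL, id = NULL, group = NULL) {
  property <- match.arg(property)
  vals <- switch(property,
                 CBT = standardize_cbt(profiles$thickness, profiles$length_mm),
                 SMA = {
                   if (is.null(mass_kg)) stop("SMA maps need mass_kg")
                   standardize_sma(profiles$sma, mass_kg, profiles$length_mm)
                 })
  if (!all(is.finite(vals))) stop("non-finite values in morphometric map")
  if (!all(dim(vals) == c(length(profiles$fractions), 360)))
    stop("map must be sections x 360")
  structure(vals, property = property, id = id, group = group,
            fractions = profiles$fractions,
            class = c("morphometric_map", "matrix", "array"))
}

check_map_list <- function(maps) {
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]])
  for (m in maps) stopifnot(all(dim(m) == d))
  invisible(d)
}

#' Consensus and coefficient-of-variation maps
#'
#' The consensus map is the pixelwise mean across a group's individual
#' maps; the CV map is the pixelwise standard deviation (n - 1 denominator)
#' divided by the pixelwise mean.  CV maps are scale invariant: multiplying
#' every individual's map by a constant leaves them unchanged.
#'
#' @param maps list of [morphometric_map()] matrices of identical shape.
#' @return a matrix of the same shape (attributes of the first map are kept
#'   where meaningful).
#' @export
consensus_map <- function(maps) {
  d <- check_map_list(maps)
  out <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  structure(out, property = attr(maps[[1]], "property"), n = length(maps),
            class = c("morphometric_map", "matrix", "array"))
}

#' @rdname consensus_map
#' @export
cv_map <- function(maps) {
  d <- check_map_list(maps)
  n <- length(maps)
  if (n < 2) stop("CV maps need at least 2 individuals")
  mu <- Reduce(`+`, lapply(maps, unclass)) / n
  ss <- Reduce(`+`, lapply(maps, function(m) (unclass(m) - mu)^2))
  sdm <- sqrt(ss / (n - 1))
  structure(sdm / mu, property = attr(maps[[1]], "property"), n = n,
            class = c("morphometric_map", "matrix", "array"))
}

#' Color-scale anchors for map visualization
#'
#' Interspecific mode extracts one global (min, max) across all group
#' consensus maps, so every group is drawn against the same range;
#' intraspecific mode uses each group's own (min, max); `cv` mode is global
#' across the group CV maps.
#'
#' @param group_maps named list (one element per group) of consensus or CV
#'   map matrices.
#' @param mode `"interspecific"`, `"intraspecific"` or `"cv"`.
#' @return named list per group of `c(min, max)` anchors.
#' @export
color_scale <- function(group_maps,
                        mode = c("interspecific", "intraspecific", "cv")) {
  mode <- match.arg(mode)
  rngs <- lapply(group_maps, range)
  if (mode %in% c("interspecific", "cv")) {
    g <- range(unlist(rngs))
    rngs <- lapply(group_maps, function(m) g)
  }
  for (nm in names(rngs))
    if (diff(rngs[[nm]]) == 0)
      warning(sprintf("degenerate color anchors for '%s' (min = max)", nm))
  rngs
}

#' Render a morphometric map to an RGB image
#'
#' Display-only smooth upsampling of the 17 x 360 data matrix (the matrix
#' itself is never altered): columns wrap in the angle dimension to avoid a
#' seam at 0/360 degrees, values are bilinearly interpolated onto a finer
#' raster, then mapped to a cold-to-hot (purple to red) ramp between the
#' supplied anchors.  Rows are drawn with section 1 (proximal) at the
#' bottom and section 17 at the top; columns start at the 0-degree
#' reference.
#'
#' @param map a map matrix (sections x degrees).
#' @param anchors `c(min, max)` color anchors (e.g. from [color_scale()]).
#' @param upsample integer display upsampling factor per axis.
#' @param palette_n number of color steps.
#' @return list with `rgb` (H x W x 3 array in \[0, 1\]), `data` (the
#'   untouched input matrix) and `anchors`.
#' @export
render_map <- function(map, anchors = range(map), upsample = 8L,
                       palette_n = 256L) {
  m <- unclass(map)
  if (diff(range(anchors)) == 0) {
    warning("degenerate anchors (min = max); rendering uniform mid-color")
    val <- matrix(0.5, nrow(m) * upsample, ncol(m) * upsample)
  } else {
    big <- upsample_torus(m, upsample)
    val <- (big - anchors[1]) / (anchors[2] - anchors[1])
    val <- matrix(pmin(1, pmax(0, val)), nrow(big), ncol(big))
  }
  ramp <- grDevices::colorRampPalette(
    c("#5E17A6", "#2A52BE", "#00B7EB", "#27C24C", "#F7E01B",
      "#F78B1B", "#D7191C"))(palette_n)
  idx <- pmin(palette_n, as.integer(val * (palette_n - 1L)) + 1L)
  col <- grDevices::col2rgb(ramp[idx]) / 255
  H <- nrow(val)            # image rows = sections, proximal drawn at bottom
  W <- ncol(val)
  rgb <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    chm <- matrix(col[ch, ], H, W)
    rgb[, , ch] <- chm[H:1, , drop = FALSE]
  }
  list(rgb = rgb, data = map, anchors = anchors)
}

# bilinear upsampling with wrap-around in the column (angle) dimension
upsample_torus <- function(m, f) {
  nr <- nrow(m)
  nc <- ncol(m)
  ro <- (seq_len(nr * f) - 0.5) / f + 0.5   # center-index row coords
  co <- (seq_len(nc * f) - 0.5) / f
  r0 <- pmin(nr - 1L, pmax(1L, floor(ro)))
  fr <- pmin(1, pmax(0, ro - r0))
  c0 <- floor(co - 0.5) + 1L
  fc <- (co - 0.5) - (c0 - 1L)
  wrap <- function(j) ((j - 1L) %% nc) + 1L
  m1 <- m[r0, wrap(c0), drop = FALSE]
  m2 <- m[pmin(nr, r0 + 1L), wrap(c0), drop = FALSE]
  m3 <- m[r0, wrap(c0 + 1L), drop = FALSE]
  m4 <- m[pmin(nr, r0 + 1L), wrap(c0 + 1L), drop = FALSE]
  FR <- matrix(fr, length(ro), length(co))
  FC <- matrix(fc, length(ro), length(co), byrow = TRUE)
  m1 * (1 - FR) * (1 - FC) + m2 * FR * (1 - FC) +
    m3 * (1 - FR) * FC + m4 * FR * FC
}

#' Write a rendered map as PNG (requires the optional png package)
#' @param rendered output of [render_map()].
#' @param path output PNG path.
#' @return `path` invisibly.
#' @export
export_map_png <- function(rendered, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("PNG export needs the 'png' package")
  png::writePNG(rendered$rgb, path)
  invisible(path)
}

#' Write a map matrix as CSV (degrees as header, fractions as row names)
#' @param map map matrix.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
export_map_csv <- function(map, path) {
  df <- as.data.frame(unclass(map))
  names(df) <- paste0("deg", seq_len(ncol(df)) - 1L)
  fr <- attr(map, "fractions")
  if (!is.null(fr)) rownames(df) <- sprintf("%.1f%%", fr)
  utils::write.csv(df, path)
  invisible(path)
}
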