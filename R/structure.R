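#' Radial structural properties of a cross section
#'
#' [section_profile()] measures one cleaned cross section: the area centroid
#' of the cortical (bone) pixels, periosteal and endosteal radii along 360
#' rays at one-degree increments (counter-clockwise, ray 0 along +x, the
#' reference/medial direction), the radial cortical thickness, and second
#' moments of area (SMA) about 360 neutral axes through the centroid at
#' one-degree increments (the axis for ray 0 is parallel to +x, so SMA
#' values repeat with a 180-degree period).
#'
#' @param section a `cross_section` (see [extract_sections()]).
#' @return a `section_profile`: list with `centroid` (mm), `periosteal_r`,
#'   `endosteal_r`, `thickness` (360 values each, mm), `sma` (360 values,
#'   mm^4), `raw_moments` (Ixx, Iyy, Ixy about centroid axes, mm^4, plus
#'   area mm^2), `fraction`, `index`.
#' @export
section_profile <- function(section) {
  ctr <- section_centroid(section)
  rad <- radial_radii(section, ctr)
  mom <- raw_moments(section, ctr)
  structure(
    list(centroid = ctr,
         periosteal_r = rad$periosteal_r,
         endosteal_r = rad$endosteal_r,
         thickness = thickness_profile(rad),
         sma = sma_from_moments(mom, 0:359),
         raw_moments = mom,
         fraction = section$fraction, index = section$index),
    class = "section_profile")
}

#' @rdname section_profile
#' @export
section_centroid <- function(section) {
  m <- section$mask
  if (!any(m)) stop("empty cortical mask")
  idx <- which(m, arr.ind = TRUE)
  a <- section$pixel_mm
  c(x = (mean(idx[, 1]) - 0.5) * a, y = (mean(idx[, 2]) - 0.5) * a)
}

#' @rdname section_profile
#' @param centroid centroid in section mm coordinates (from
#'   [section_centroid()]).
#' @param step_px ray-marching step as a fraction of a pixel.
#' @export
radial_radii <- function(section, centroid = section_centroid(section),
                         step_px = 0.25) {
  m <- section$mask
  a <- section$pixel_mm
  idx <- which(m, arr.ind = TRUE)
  dx <- (idx[, 1] - 0.5) * a - centroid[1]
  dy <- (idx[, 2] - 0.5) * a - centroid[2]
  rmax <- sqrt(max(dx^2 + dy^2)) + 2 * a
  rs <- seq(0, rmax, by = step_px * a)
  th <- (0:359) * pi / 180
  # occupancy sampled by bilinear interpolation of the binary mask: the 0.5
  # level is the subpixel boundary estimate
  px <- outer(cos(th), rs) + centroid[1]
  py <- outer(sin(th), rs) + centroid[2]
  v <- bilinear_mat(m * 1, px / a + 0.5, py / a + 0.5)
  dim(v) <- dim(px)
  peri <- numeric(360)
  endo <- numeric(360)
  nr <- length(rs)
  dr <- rs[2] - rs[1]
  for (i in 1:360) {
    vi <- v[i, ]
    inside <- vi >= 0.5
    if (!any(inside))
      stop(sprintf("ray %d has no boundary crossing", i - 1L))
    last_in <- max(which(inside))
    if (last_in == nr) last_in <- nr - 1L
    peri[i] <- cross_refine(rs, vi, last_in)
    if (inside[1]) {
      endo[i] <- 0
    } else {
      first_in <- min(which(inside))
      endo[i] <- cross_refine(rs, vi, first_in - 1L)
    }
  }
  list(periosteal_r = peri, endosteal_r = endo)
}

# linear refinement of the 0.5 crossing between samples j and j+1
cross_refine <- function(rs, v, j) {
  v0 <- v[j]
  v1 <- v[j + 1]
  if (abs(v1 - v0) < 1e-12) return(rs[j])
  rs[j] + (0.5 - v0) / (v1 - v0) * (rs[j + 1] - rs[j])
}

bilinear_mat <- function(m, xi, yi) {
  nr <- nrow(m)
  nc <- ncol(m)
  x0 <- floor(xi)
  y0 <- floor(yi)
  fx <- xi - x0
  fy <- yi - y0
  gv <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    out <- numeric(length(i))
    out[ok] <- m[cbind(i[ok], j[ok])]
    out
  }
  i0 <- as.integer(x0); j0 <- as.integer(y0)
  gv(i0, j0) * (1 - fx) * (1 - fy) + gv(i0 + 1L, j0) * fx * (1 - fy) +
    gv(i0, j0 + 1L) * (1 - fx) * fy + gv(i0 + 1L, j0 + 1L) * fx * fy
}

#' @rdname section_profile
#' @param radii output of [radial_radii()].
#' @export
thickness_profile <- function(radii) {
  t <- radii$periosteal_r - radii$endosteal_r
  pmax(t, 0)
}

#' @rdname section_profile
#' @export
raw_moments <- function(section, centroid = section_centroid(section)) {
  m <- section$mask
  a <- section$pixel_mm
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty cortical mask")
  x <- (idx[, 1] - 0.5) * a - centroid[1]
  y <- (idx[, 2] - 0.5) * a - centroid[2]
  n <- nrow(idx)
  self <- n * a^4 / 12          # per-pixel self moment about its own center
  list(Ixx = sum(y^2) * a^2 + self,
       Iyy = sum(x^2) * a^2 + self,
       Ixy = sum(x * y) * a^2,
       area = n * a^2)
}

#' @rdname section_profile
#' @param moments raw moments list (Ixx, Iyy, Ixy).
#' @param theta_deg neutral-axis angles in degrees.
#' @export
sma_from_moments <- function(moments, theta_deg = 0:359) {
  th <- theta_deg * pi / 180
  moments$Ixx * cos(th)^2 + moments$Iyy * sin(th)^2 -
    2 * moments$Ixy * sin(th) * cos(th)
}

#' @rdname section_profile
#' @export
sma_profile <- function(section, centroid = section_centroid(section)) {
  sma_from_moments(raw_moments(section, centroid), 0:359)
}

#' Measure a full rendering: 17 sections, 720 radii each
#'
#' Runs [extract_sections()] and [section_profile()] over a positioned
#' rendering and stacks the per-section results into 17 x 360 matrices
#' (rows proximal to distal, columns degrees counter-clockwise from the
#' reference direction).
#'
#' @inheritParams extract_sections
#' @param ... passed to [extract_sections()].
#' @return a `bone_profiles` object: `thickness`, `periosteal_r`,
#'   `endosteal_r`, `sma` (17 x 360 matrices), `profiles` (list of
#'   [section_profile()]), `length_mm`, `fractions`, `meta`.
#' @export
measure_rendering <- function(rendering, ...) {
  secs <- extract_sections(rendering, ...)
  profs <- lapply(secs, section_profile)
  stack <- function(field)
    do.call(rbind, lapply(profs, `[[`, field))
  structure(
    list(thickness = stack("thickness"),
         periosteal_r = stack("periosteal_r"),
         endosteal_r = stack("endosteal_r"),
         sma = stack("sma"),
         profiles = profs,
         length_mm = mechanical_length(rendering),
         fractions = vapply(secs, `[[`, numeric(1), "fraction"),
         meta = rendering$meta),
    class = "bone_profiles")
}

#' Export per-individual profiles as CSV
#'
#' One file per property: 17 rows x 360 columns, header row of degrees and
#' row labels of fraction length.
#'
#' @param profiles a `bone_profiles` object.
#' @param dir output directory.
#' @param id individual identifier used in file names.
#' @return invisibly, the written paths.
#' @export
export_profiles_csv <- function(profiles, dir, id = "individual") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (prop in c("thickness", "periosteal_r", "endosteal_r", "sma")) {
    m <- profiles[[prop]]
    df <- as.data.frame(m)
    names(df) <- paste0("deg", 0:359)
    rownames(df) <- sprintf("%.1f%%", profiles$fractions)
    p <- file.path(dir, sprintf("%s_%s.csv", id, prop))
    utils::write.csv(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
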