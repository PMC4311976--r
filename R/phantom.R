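#' Specify a hollow-bone phantom
#'
#' A phantom is an idealized diaphysis: a closed tube whose outer (periosteal)
#' radius and radial wall thickness vary with angular position and fractional
#' length.  Both functions are evaluated in the phantom's *material* frame
#' (angle 0 along +x, counter-clockwise, before any roll or mirroring), must
#' be vectorized over the angle argument, and return mm.
#'
#' @param length_mm tube length (mechanical length) in mm.
#' @param outer_radius_fn `function(angle_deg, fraction_length)` -> outer
#'   radius in mm.
#' @param wall_thickness_fn `function(angle_deg, fraction_length)` -> radial
#'   wall thickness in mm; must be strictly positive and smaller than the
#'   outer radius everywhere.
#' @param voxel_mm isotropic voxel size (mm); must be at most half the
#'   minimum wall thickness so the wall is sampled adequately.
#' @param roll_offset_deg rotation of the phantom about its long axis applied
#'   at generation time (the positioning protocol has to undo it).
#' @param noise_sd_mm standard deviation of a smooth angular perturbation
#'   (low-order Fourier harmonics) added to the outer radius; the wall
#'   follows the outer surface, so radial thickness is unaffected.
#' @param side `"left"` or `"right"`; right phantoms are generated as mirror
#'   images (reflection of x) to exercise the mirroring step.
#' @param seed integer RNG seed; identical specs with identical seeds give
#'   bit-identical voxel grids.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(length_mm, outer_radius_fn, wall_thickness_fn,
                         voxel_mm = 0.3, roll_offset_deg = 0,
                         noise_sd_mm = 0, side = "left", seed = 1L) {
  stopifnot(is.numeric(length_mm), length_mm > 0,
            is.function(outer_radius_fn), is.function(wall_thickness_fn),
            voxel_mm > 0, noise_sd_mm >= 0)
  side <- match.arg(side, c("left", "right"))
  spec <- structure(
    list(length_mm = length_mm, outer_radius_fn = outer_radius_fn,
         wall_thickness_fn = wall_thickness_fn, voxel_mm = voxel_mm,
         roll_offset_deg = roll_offset_deg, noise_sd_mm = noise_sd_mm,
         side = side, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec, outer_fn = spec$outer_radius_fn) {
  ang <- seq(0, 359.5, by = 0.5)
  fr <- seq(0, 1, by = 0.025)
  for (f in fr) {
    ro <- outer_fn(ang, f)
    w <- spec$wall_thickness_fn(ang, f)
    if (any(!is.finite(ro)) || any(!is.finite(w)))
      stop("phantom radius/thickness functions returned non-finite values")
    if (any(w <= 0))
      stop("degenerate phantom: wall thickness must be strictly positive")
    if (any(w >= ro))
      stop("degenerate phantom: wall thickness must be smaller than the outer radius")
  }
  wmin <- min(vapply(fr, function(f) min(spec$wall_thickness_fn(ang, f)),
                     numeric(1)))
  if (spec$voxel_mm > wmin / 2)
    stop(sprintf(
      "voxel_mm = %.3g undersamples the wall (min thickness %.3g mm); need voxel_mm <= %.3g",
      spec$voxel_mm, wmin, wmin / 2))
  invisible(spec)
}

#' Radial coordinate of an axis-aligned ellipse boundary
#'
#' @param a,b semi-axes along x and y (mm).
#' @param angle_deg polar angle(s), degrees counter-clockwise from +x.
#' @return radius of the ellipse boundary at each angle.
#' @export
ellipse_radius <- function(a, b, angle_deg) {
  th <- angle_deg * pi / 180
  a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
}

#' Convenience constructors for tube geometry functions
#'
#' `tube_circular()` gives a constant outer radius and wall;
#' `tube_elliptical()` gives elliptical outer and inner boundaries (the wall
#' function is the radial distance between the two ellipses).
#'
#' @param outer_r,wall constant radius / wall thickness (mm).
#' @return list with vectorized `outer` and `wall` functions.
#' @export
tube_circular <- function(outer_r, wall) {
  list(outer = function(angle_deg, fraction_length)
         rep_len(outer_r, length(angle_deg)),
       wall = function(angle_deg, fraction_length)
         rep_len(wall, length(angle_deg)))
}

#' @rdname tube_circular
#' @param a_out,b_out,a_in,b_in semi-axes of outer and inner ellipses (mm).
#' @export
tube_elliptical <- function(a_out, b_out, a_in, b_in) {
  stopifnot(a_in < a_out, b_in < b_out)
  list(outer = function(angle_deg, fraction_length)
         ellipse_radius(a_out, b_out, angle_deg),
       wall = function(angle_deg, fraction_length)
         ellipse_radius(a_out, b_out, angle_deg) -
           ellipse_radius(a_in, b_in, angle_deg))
}

# Smooth angular noise field: low-order Fourier series with continuous
# standard deviation noise_sd (0 harmonics -> identically zero).
make_noise_fn <- function(noise_sd, n_harmonics = 4L) {
  if (noise_sd <= 0) return(function(angle_deg) rep_len(0, length(angle_deg)))
  a <- rnorm(n_harmonics)
  b <- rnorm(n_harmonics)
  scale <- noise_sd / sqrt(sum(a^2 + b^2) / 2)
  a <- a * scale
  b <- b * scale
  function(angle_deg) {
    th <- angle_deg * pi / 180
    out <- numeric(length(th))
    for (k in seq_len(n_harmonics))
      out <- out + a[k] * cos(k * th) + b[k] * sin(k * th)
    out
  }
}

#' Generate a voxelized phantom with analytic ground truth
#'
#' Voxelization is a center-of-voxel membership test against the analytic
#' tube (no anti-aliasing), matching binary segmented renderings.  The
#' returned volume carries landmarks at the tube-axis endpoints plus a roll
#' reference marking the phantom's intrinsic 90-degree (dorsal) direction,
#' and `truth` fields: the exact radial thickness map and the exact second
#' moment of area (SMA) map on the 17 x 360 measurement grid, both computed
#' analytically (SMA by dense quadrature of the boundary functions, 14400
#' angular samples per section) before voxelization.  Truth maps are always
#' expressed in the material (left-form, roll-free) frame.
#'
#' @param spec a [phantom_spec()].
#' @return a [bone_volume()] with `landmarks`, `meta$side` and `truth`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  noise_fn <- withr::with_seed(spec$seed, make_noise_fn(spec$noise_sd_mm))
  outer_eff <- function(angle_deg, fraction_length)
    spec$outer_radius_fn(angle_deg, fraction_length) + noise_fn(angle_deg)
  validate_phantom_spec(spec, outer_fn = outer_eff)

  vox <- spec$voxel_mm
  L <- spec$length_mm
  ang_chk <- seq(0, 359.5, by = 0.5)
  rmax <- max(vapply(seq(0, 1, by = 0.05),
                     function(f) max(outer_eff(ang_chk, f)), numeric(1)))
  r_ref <- rmax + 0.8
  half <- r_ref + 2 * vox + 0.5
  nx <- 2L * as.integer(ceiling(half / vox))
  nz <- as.integer(round(L / vox))
  origin <- c(-nx * vox / 2, -nx * vox / 2, 0)

  xs <- origin[1] + (seq_len(nx) - 0.5) * vox
  X <- matrix(xs, nx, nx)
  Y <- matrix(xs, nx, nx, byrow = TRUE)
  phi <- (atan2(Y, X) * 180 / pi) %% 360
  psi <- if (spec$side == "right")
    (180 - (phi - spec$roll_offset_deg)) %% 360
  else
    (phi - spec$roll_offset_deg) %% 360
  rr <- sqrt(X^2 + Y^2)

  mask <- array(FALSE, c(nx, nx, nz))
  zc <- (seq_len(nz) - 0.5) * vox
  pa <- as.vector(psi)
  for (k in seq_len(nz)) {
    f <- zc[k] / L
    ro <- outer_eff(pa, f)
    ri <- ro - spec$wall_thickness_fn(pa, f)
    mask[, , k] <- rr <= ro & rr > ri
  }

  a_ref <- (90 + spec$roll_offset_deg) * pi / 180
  landmarks <- list(
    proximal = c(0, 0, 0),
    distal = c(0, 0, L),
    roll_ref = c(r_ref * cos(a_ref), r_ref * sin(a_ref), min(vox, L)))

  bone_volume(mask, vox, origin, landmarks = landmarks,
              meta = list(side = spec$side),
              truth = phantom_truth(spec, outer_eff))
}

# Analytic truth maps on the 17 x 360 grid (material frame).
phantom_truth <- function(spec, outer_eff, n_quad = 14400L) {
  fractions <- seq(25, 65, by = 2.5)
  angles <- 0:359
  th <- angles * pi / 180
  thickness <- t(vapply(fractions / 100,
                        function(f) spec$wall_thickness_fn(angles, f),
                        numeric(360)))
  aq <- (seq_len(n_quad) - 1) * (360 / n_quad)
  dphi <- 2 * pi / n_quad
  cq <- cos(aq * pi / 180)
  sq <- sin(aq * pi / 180)
  sma <- matrix(0, length(fractions), 360)
  centroid <- matrix(0, length(fractions), 2)
  for (i in seq_along(fractions)) {
    f <- fractions[i] / 100
    ro <- outer_eff(aq, f)
    ri <- ro - spec$wall_thickness_fn(aq, f)
    A <- sum((ro^2 - ri^2) / 2) * dphi
    cx <- sum((ro^3 - ri^3) / 3 * cq) * dphi / A
    cy <- sum((ro^3 - ri^3) / 3 * sq) * dphi / A
    ixx <- sum((ro^4 - ri^4) / 4 * sq^2) * dphi - A * cy^2
    iyy <- sum((ro^4 - ri^4) / 4 * cq^2) * dphi - A * cx^2
    ixy <- sum((ro^4 - ri^4) / 4 * sq * cq) * dphi - A * cx * cy
    sma[i, ] <- ixx * cos(th)^2 + iyy * sin(th)^2 - 2 * ixy * sin(th) * cos(th)
    centroid[i, ] <- c(cx, cy)
  }
  list(thickness = thickness, sma = sma, centroid = centroid,
       fractions = fractions, angles_deg = angles)
}

#' Specify a multi-group phantom cohort
#'
#' Each group is a [phantom_group()]; between-individual variation is a
#' multiplicative lognormal jitter on wall thickness and overall size plus
#' additive angular phase jitter, and (optionally) a lognormally variable
#' local thickening ("bump").  The default three-group design (see
#' [default_cohort_spec()]) plants the kinds of differences the measurement
#' pipeline is meant to detect.
#'
#' @param groups list of [phantom_group()] objects.
#' @param seed integer seed governing all cohort-level randomness.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, seed = 1L) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "phantom_group")))
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("group labels must be unique")
  for (g in groups) if (g$n < 2) stop("each group needs n >= 2 individuals")
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param label group label.
#' @param n number of individuals (>= 2).
#' @param length_mm mean mechanical length (mm).
#' @param outer_r0 mean outer radius (mm).
#' @param elong relative outer-contour elongation amplitude (cos 2-theta).
#' @param elong_axis_deg angular position of the long axis of the contour
#'   (90 = dorsoplantar under the map convention 0 = medial, 90 = dorsal).
#' @param wall_mm mean radial wall thickness (mm).
#' @param bump optional local thickening: list with `center_deg`,
#'   `center_frac`, `width_deg`, `width_frac`, `amp_mean` (mm) and
#'   `amp_sdlog` (lognormal spread of the amplitude between individuals).
#' @param wall_sdlog,size_sdlog lognormal jitter (sdlog) of wall thickness
#'   and overall size between individuals.
#' @param phase_sd_deg angular phase jitter (sd, degrees) between individuals.
#' @param right_fraction probability an individual is a right-sided element.
#' @param mass_kg named vector `c(M = , F = )` of mean body mass by sex (kg).
#' @param noise_sd_mm outer-surface noise passed to [phantom_spec()].
#' @param voxel_mm voxel size for this group's phantoms.
#' @export
phantom_group <- function(label, n, length_mm = 60, outer_r0 = 5.5,
                          elong = 0.05, elong_axis_deg = 0, wall_mm = 2.5,
                          bump = NULL, wall_sdlog = 0.08, size_sdlog = 0.05,
                          phase_sd_deg = 4, right_fraction = 0.4,
                          mass_kg = c(M = 50, F = 42), noise_sd_mm = 0.12,
                          voxel_mm = 0.3) {
  stopifnot(n >= 1, length_mm > 0, outer_r0 > 0, wall_mm > 0)
  structure(as.list(environment()), class = "phantom_group")
}

#' The default three-group study cohort
#'
#' Emulates a 43-individual, three-species comparative sample: two thick-
#' walled "ape-like" groups (A and B, n = 14 each; B adds a plantar-proximal
#' local thickening whose amplitude varies strongly between individuals,
#' creating a coefficient-of-variation hot spot near 270 degrees) and a
#' thin-walled, dorsoplantarly elongated "human-like" group (C, n = 15).
#'
#' @param seed cohort seed.
#' @param voxel_mm voxel size used for every phantom.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, voxel_mm = 0.3) {
  cohort_spec(list(
    phantom_group("A", 14, length_mm = 58, outer_r0 = 5.6, elong = 0.06,
                  elong_axis_deg = 0, wall_mm = 2.6,
                  mass_kg = c(M = 50, F = 41), voxel_mm = voxel_mm),
    phantom_group("B", 14, length_mm = 62, outer_r0 = 6.0, elong = 0.06,
                  elong_axis_deg = 0, wall_mm = 2.8,
                  bump = list(center_deg = 270, center_frac = 0.32,
                              width_deg = 28, width_frac = 0.10,
                              amp_mean = 1.2, amp_sdlog = 0.5),
                  mass_kg = c(M = 170, F = 72), voxel_mm = voxel_mm),
    phantom_group("C", 15, length_mm = 60, outer_r0 = 6.2, elong = 0.18,
                  elong_axis_deg = 90, wall_mm = 1.6,
                  mass_kg = c(M = 62, F = 53), voxel_mm = voxel_mm)),
    seed = seed)
}

#' Generate a phantom cohort
#'
#' Draws per-individual geometry, sex, side, body mass and phantom seeds from
#' the cohort seed, then voxelizes each phantom.  Two calls with the same
#' spec produce identical metadata tables and volumes.
#'
#' @param spec a [cohort_spec()].
#' @param keep_volumes if `FALSE`, return only metadata and specs (volumes
#'   generated lazily by the caller).
#' @return list with `volumes` (list of [bone_volume()]), `metadata`
#'   (data.frame: id, group, sex, side, mass_kg, length_mm, seed) and
#'   `specs` (list of [phantom_spec()]).
#' @export
generate_cohort <- function(spec, keep_volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  draws <- withr::with_seed(spec$seed, {
    lapply(spec$groups, function(g) {
      lapply(seq_len(g$n), function(i) {
        list(sex = sample(c("M", "F"), 1),
             side = if (runif(1) < g$right_fraction) "right" else "left",
             len_mult = rlnorm(1, 0, 0.04),
             size_mult = rlnorm(1, 0, g$size_sdlog),
             wall_mult = rlnorm(1, 0, g$wall_sdlog),
             phase = rnorm(1, 0, g$phase_sd_deg),
             bump_amp = if (!is.null(g$bump))
               rlnorm(1, log(g$bump$amp_mean), g$bump$amp_sdlog) else 0,
             mass_mult = rlnorm(1, 0, 0.06),
             roll = runif(1, -15, 15),
             seed = sample.int(2147483646L, 1))
      })
    })
  })

  meta <- list()
  specs <- list()
  idx <- 0L
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    for (i in seq_len(g$n)) {
      idx <- idx + 1L
      d <- draws[[gi]][[i]]
      specs[[idx]] <- individual_phantom_spec(g, d)
      meta[[idx]] <- data.frame(
        id = sprintf("%s%02d", g$label, i), group = g$label, sex = d$sex,
        side = d$side, mass_kg = unname(g$mass_kg[d$sex] * d$mass_mult),
        length_mm = g$length_mm * d$len_mult, seed = d$seed,
        stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  vols <- if (keep_volumes) lapply(specs, generate_phantom) else NULL
  list(volumes = vols, metadata = metadata, specs = specs)
}

# Build one individual's phantom_spec from group parameters and jitter draws.
individual_phantom_spec <- function(g, d) {
  r0 <- g$outer_r0 * d$size_mult
  elong <- g$elong
  axis <- g$elong_axis_deg + d$phase
  wall0 <- g$wall_mm * d$wall_mult
  bump <- g$bump
  bump_amp <- d$bump_amp
  bump_center <- if (!is.null(bump)) bump$center_deg + d$phase else 0
  outer_fn <- function(angle_deg, fraction_length) {
    r0 * (1 + elong * cos(2 * (angle_deg - axis) * pi / 180))
  }
  wall_fn <- function(angle_deg, fraction_length) {
    w <- rep_len(wall0, length(angle_deg))
    if (!is.null(bump) && bump_amp > 0) {
      da <- ((angle_deg - bump_center + 180) %% 360) - 180
      w <- w + bump_amp * exp(-(da / bump$width_deg)^2 -
                                ((fraction_length - bump$center_frac) /
                                   bump$width_frac)^2)
    }
    # keep a patent medullary canal whatever the jitter draws
    pmin(w, 0.85 * outer_fn(angle_deg, fraction_length))
  }
  phantom_spec(length_mm = g$length_mm * d$len_mult,
               outer_radius_fn = outer_fn, wall_thickness_fn = wall_fn,
               voxel_mm = g$voxel_mm, roll_offset_deg = d$roll,
               noise_sd_mm = g$noise_sd_mm, side = d$side, seed = d$seed)
}
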