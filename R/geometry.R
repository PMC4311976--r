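#' Positioning protocol for bone volumes
#'
#' [align_to_axis()] applies the landmark-based positioning protocol: the
#' line through the proximal and distal articular-surface landmarks is made
#' parallel to the z axis (proximal at lower z), the volume is resliced onto
#' a new axis-aligned grid, and the inter-landmark z distance is recorded as
#' mechanical length.  [fix_roll()] then rotates about z until the roll
#' reference direction parallels +y, and [mirror_if_right()] reflects
#' right-sided elements across x so all individuals are compared in left
#' form.  Rotation and translation are composed into a single rigid
#' transform and applied in one nearest-neighbour reslicing pass.
#'
#' @param vol a [bone_volume()] with landmarks.
#' @param landmarks optional landmark list overriding `vol$landmarks`.
#' @return an aligned [bone_volume()] (classes `aligned_rendering`,
#'   `bone_volume`) with `length_mm`, transformed landmarks, and the axis on
#'   x = y = 0 with the proximal landmark at z = 0.
#' @export
align_to_axis <- function(vol, landmarks = NULL) {
  lm <- landmarks %||% vol$landmarks
  if (is.null(lm)) stop("no landmarks available")
  validate_landmarks(lm)
  d <- lm$distal - lm$proximal
  len <- sqrt(sum(d^2))
  if (len < vol$voxel_mm) stop("landmarks coincide (degenerate axis)")
  R <- rotation_to_z(d / len)
  out <- apply_rigid(vol, R, center = lm$proximal)
  out$length_mm <- len
  out$meta <- vol$meta
  class(out) <- c("aligned_rendering", class(out))
  out
}

#' @rdname align_to_axis
#' @param rendering an aligned rendering (output of [align_to_axis()]).
#' @export
fix_roll <- function(rendering) {
  stopifnot(inherits(rendering, "aligned_rendering"))
  lm <- rendering$landmarks
  if (is.null(lm$roll_ref)) stop("no roll reference landmark")
  w <- lm$roll_ref[1:2] - lm$proximal[1:2]
  if (sqrt(sum(w^2)) < rendering$voxel_mm / 2)
    stop("roll reference lies on the longitudinal axis; roll is undefined")
  ang <- atan2(w[2], w[1])
  delta <- pi / 2 - ang
  R <- rot_z(delta)
  out <- apply_rigid(rendering, R, center = lm$proximal)
  out$length_mm <- rendering$length_mm
  out$meta <- rendering$meta
  out$roll_fixed <- TRUE
  class(out) <- class(rendering)
  out
}

#' @rdname align_to_axis
#' @export
mirror_if_right <- function(rendering) {
  stopifnot(inherits(rendering, "bone_volume"))
  side <- rendering$meta$side %||% "left"
  mirrored <- isTRUE(rendering$mirrored)
  if (side != "right") return(rendering)
  out <- rendering
  n1 <- dim(rendering$mask)[1]
  out$mask <- rendering$mask[n1:1, , , drop = FALSE]
  # reflect physical x about 0: voxel i had center o1 + (i - .5) v; after the
  # index flip its center must be the negation of the old one.
  xmax <- rendering$origin[1] + n1 * rendering$voxel_mm
  out$origin[1] <- -xmax
  refl <- function(p) c(-p[1], p[2], p[3])
  out$landmarks <- lapply(rendering$landmarks, refl)
  out$mirrored <- !mirrored
  out
}

#' @rdname align_to_axis
#' @export
mechanical_length <- function(rendering) {
  if (!is.null(rendering$length_mm)) return(rendering$length_mm)
  lm <- rendering$landmarks
  if (is.null(lm)) stop("no landmarks available")
  abs(lm$distal[3] - lm$proximal[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rotation matrix taking unit vector u onto +z (Rodrigues construction).
rotation_to_z <- function(u) {
  ez <- c(0, 0, 1)
  c_ <- sum(u * ez)
  v <- c(u[2], -u[1], 0)              # u x ez
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))        # 180 deg about x
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

#' Apply a rigid transform to a volume and reslice
#'
#' Maps physical point `p` to `R %*% (p - center)`, so `center` lands at the
#' output origin (0, 0, 0).  The output grid is axis-aligned with the same
#' voxel size, covering the transformed bounding box; binary masks are
#' resampled by nearest neighbour (no fractional labels).  When the
#' transform is the identity the volume is returned untouched (single
#' interpolation pass is skipped).
#'
#' @param vol a [bone_volume()].
#' @param R 3x3 rotation matrix.
#' @param center physical point mapped to the output origin.
#' @return transformed [bone_volume()].
#' @keywords internal
#' @export
apply_rigid <- function(vol, R, center = c(0, 0, 0)) {
  vox <- vol$voxel_mm
  if (max(abs(R - diag(3))) < 1e-9) {
    out <- vol
    out$origin <- vol$origin - center
    out$landmarks <- lapply(vol$landmarks, function(p) p - center)
    return(out)
  }
  d <- dim(vol$mask)
  corners <- as.matrix(expand.grid(c(0, d[1]), c(0, d[2]), c(0, d[3])))
  corners <- sweep(corners * vox, 2, -vol$origin)  # physical corners
  tc <- t(R %*% (t(corners) - center))
  lo <- apply(tc, 2, min) - vox
  hi <- apply(tc, 2, max) + vox
  nd <- as.integer(ceiling((hi - lo) / vox))
  origin <- lo

  Rt <- t(R)
  xs <- origin[1] + (seq_len(nd[1]) - 0.5) * vox
  ys <- origin[2] + (seq_len(nd[2]) - 0.5) * vox
  XY <- cbind(rep(xs, times = nd[2]), rep(ys, each = nd[1]))
  mask <- array(FALSE, nd)
  for (k in seq_len(nd[3])) {
    z <- origin[3] + (k - 0.5) * vox
    # inverse map: p = R' q + center
    P <- XY %*% t(Rt[1:2, 1:2])
    px <- P[, 1] + Rt[1, 3] * z + center[1]
    py <- P[, 2] + Rt[2, 3] * z + center[2]
    pz <- XY %*% Rt[3, 1:2] + Rt[3, 3] * z + center[3]
    i <- as.integer(floor((px - vol$origin[1]) / vox)) + 1L
    j <- as.integer(floor((py - vol$origin[2]) / vox)) + 1L
    kk <- as.integer(floor((pz - vol$origin[3]) / vox)) + 1L
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & kk >= 1L & kk <= d[3]
    vals <- logical(nrow(XY))
    if (any(ok))
      vals[ok] <- vol$mask[cbind(i[ok], j[ok], kk[ok])]
    mask[, , k] <- vals
  }
  lm <- lapply(vol$landmarks, function(p) as.numeric(R %*% (p - center)))
  bone_volume(mask, vox, origin, landmarks = lm, meta = vol$meta,
              truth = vol$truth)
}
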