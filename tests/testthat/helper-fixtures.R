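# In-code fixtures: analytic cross sections, small phantoms and synthetic
# map cohorts.  Everything is generated deterministically at test time.

# Binary annulus (or solid disk with r = 0) cross section built from pixel
# centers; optionally off-center outer and inner circles.
annulus_section <- function(R = 5, r = 3, a = 0.1, pad = 1,
                            inner_center = c(0, 0)) {
  half <- R + pad
  n <- as.integer(ceiling(2 * half / a))
  xs <- (seq_len(n) - 0.5) * a - n * a / 2
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  d_out <- sqrt(X^2 + Y^2)
  d_in <- sqrt((X - inner_center[1])^2 + (Y - inner_center[2])^2)
  mask <- d_out <= R & (r <= 0 | d_in > r)
  structure(list(mask = mask, pixel_mm = a, fraction = 50, index = 9),
            class = "cross_section")
}

# irregular blob mask for moment-identity tests; a central disk guarantees
# the centroid has bone along every ray
blob_section <- function(seed = 1, n = 60, a = 0.1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * n), n, n)
    k <- outer(dnorm(seq(-3, 3, length.out = 13)),
               dnorm(seq(-3, 3, length.out = 13)))
    sm <- cortmap:::filter2_zero(m, k / sum(k))
    mask <- sm > stats::quantile(sm, 0.6)
    ctr <- (n / 2 - 0.5)
    D <- outer(seq_len(n) - 0.5 - ctr, seq_len(n) - 0.5 - ctr,
               function(x, y) sqrt(x^2 + y^2))
    mask <- mask | D < n / 5
    mask <- suppressWarnings(cortmap:::keep_largest_component(mask))
    structure(list(mask = mask, pixel_mm = a, fraction = 50, index = 9),
              class = "cross_section")
  })
}

# small bumpy-wall phantom spec for geometry tests; bump spans all fractions
small_phantom_spec <- function(roll = 0, side = "left", seed = 3,
                               bump_deg = 0, bump_amp = 0.8, noise = 0,
                               voxel = 0.25, L = 20) {
  outer_fn <- function(angle_deg, fraction_length)
    rep_len(4, length(angle_deg))
  wall_fn <- function(angle_deg, fraction_length) {
    da <- ((angle_deg - bump_deg + 180) %% 360) - 180
    1.3 + bump_amp * exp(-(da / 25)^2)
  }
  phantom_spec(L, outer_fn, wall_fn, voxel_mm = voxel,
               roll_offset_deg = roll, noise_sd_mm = noise, side = side,
               seed = seed)
}

# circular lag maximizing cross-correlation between two 360-profiles
best_circular_shift <- function(x, y) {
  cc <- vapply(0:359, function(s)
    sum(x * y[((0:359 + s) %% 360) + 1]), numeric(1))
  which.max(cc) - 1L
}

# synthetic 17 x 360 map cohort (no voxelization) with a planted patch
# difference between two groups
synthetic_map_cohort <- function(n_per_group = 12, noise_sd = 0.002,
                                 patch_amp = 0.01, seed = 5,
                                 patch_rows = 6:10, patch_cols = 80:120,
                                 groups = c("g1", "g2")) {
  withr::with_seed(seed, {
    base <- outer(seq(0.03, 0.05, length.out = 17),
                  1 + 0.1 * cos((0:359) * pi / 180))
    maps <- list()
    labels <- character(0)
    for (g in seq_along(groups)) {
      for (i in seq_len(n_per_group)) {
        m <- base + matrix(rnorm(17 * 360, 0, noise_sd), 17, 360)
        if (g == 2) m[patch_rows, patch_cols] <- m[patch_rows, patch_cols] + patch_amp
        maps[[length(maps) + 1]] <- m
        labels <- c(labels, groups[g])
      }
    }
    list(maps = maps, labels = labels,
         patch = {
           p <- matrix(FALSE, 17, 360)
           p[patch_rows, patch_cols] <- TRUE
           p
         })
  })
}

iou <- function(a, b) sum(a & b) / sum(a | b)

circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
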