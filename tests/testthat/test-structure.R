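test_that("annulus radii are recovered within half a pixel, 720 per section", {
  sec <- annulus_section(R = 5, r = 3, a = 0.1)
  ctr <- section_centroid(sec)
  rad <- radial_radii(sec, ctr)
  expect_length(rad$periosteal_r, 360L)
  expect_length(rad$endosteal_r, 360L)
  expect_equal(length(rad$periosteal_r) + length(rad$endosteal_r), 720L)
  expect_lt(max(abs(rad$periosteal_r - 5)), 0.05)
  expect_lt(max(abs(rad$endosteal_r - 3)), 0.05)
  expect_lt(max(abs(thickness_profile(rad) - 2)), 0.1)
})

test_that("a solid rod has zero endosteal radius and thickness = periosteal", {
  disk <- annulus_section(R = 4, r = 0, a = 0.1)
  rad <- radial_radii(disk)
  expect_true(all(rad$endosteal_r == 0))
  expect_equal(thickness_profile(rad), rad$periosteal_r)
})

test_that("axis-aligned ellipse: periosteal radius at 0 deg is the semi-major axis", {
  a_o <- 6; b_o <- 4
  n <- 140
  xs <- (seq_len(n) - 0.5) * 0.1 - n * 0.1 / 2
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  mask <- (X / a_o)^2 + (Y / b_o)^2 <= 1
  sec <- structure(list(mask = mask, pixel_mm = 0.1), class = "cross_section")
  rad <- radial_radii(sec)
  expect_lt(abs(rad$periosteal_r[1] - a_o), 0.06)
  expect_lt(abs(rad$periosteal_r[91] - b_o), 0.06)
})

test_that("eccentric-canal thickness matches the analytic offset-circle oracle", {
  R <- 5; r <- 2; d <- c(1.2, -0.6)
  sec <- annulus_section(R = R, r = r, a = 0.1, inner_center = d)
  ctr <- section_centroid(sec)
  rad <- radial_radii(sec, ctr)
  # the oracle works in the frame where the outer circle is centered at 0
  ctr <- unname(ctr) - nrow(sec$mask) * sec$pixel_mm / 2
  # oracle: ray from the measured centroid c in direction u; crossing with a
  # circle centered at p, radius rho: smallest/largest positive root of
  # |c + t u - p|^2 = rho^2
  ray_cross <- function(c0, u, p, rho, outermost) {
    q <- c0 - p
    b <- sum(q * u)
    disc <- b^2 - (sum(q^2) - rho^2)
    if (disc < 0) return(NA_real_)
    ts <- c(-b - sqrt(disc), -b + sqrt(disc))
    ts <- ts[ts > 0]
    if (!length(ts)) return(NA_real_)
    if (outermost) max(ts) else min(ts)
  }
  for (ang in seq(0, 350, by = 10)) {
    u <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    tp <- ray_cross(ctr, u, c(0, 0), R, TRUE)
    te <- ray_cross(ctr, u, d, r, FALSE)
    expect_lt(abs(rad$periosteal_r[ang + 1] - tp), 0.07)
    expect_lt(abs(rad$endosteal_r[ang + 1] - te), 0.07)
  }
})

test_that("centroid is symmetric, translation-equivariant, and a pixel mean", {
  sec <- annulus_section(R = 4, r = 2, a = 0.1)
  n <- nrow(sec$mask)
  ctr <- section_centroid(sec)
  expect_equal(unname(ctr), rep((n / 2) * 0.1, 2), tolerance = 1e-6)
  # translate the mask +3 px in x, -2 px in y
  sh <- sec
  sh$mask <- matrix(FALSE, n, n)
  sh$mask[4:n, 1:(n - 2)] <- sec$mask[1:(n - 3), 3:n]
  ctr2 <- section_centroid(sh)
  expect_equal(unname(ctr2 - ctr), c(0.3, -0.2), tolerance = 1e-9)
  # crescent: equals the mean of bone pixel centers computed directly
  cres <- sec
  cres$mask[, 1:(n %/% 2)] <- FALSE
  idx <- which(cres$mask, arr.ind = TRUE)
  expect_equal(unname(section_centroid(cres)),
               c((mean(idx[, 1]) - 0.5) * 0.1, (mean(idx[, 2]) - 0.5) * 0.1))
})

test_that("annulus SMA matches the closed form within 2% at 0.1 mm pixels", {
  sec <- annulus_section(R = 5, r = 3, a = 0.1)
  sma <- sma_profile(sec)
  expect_lt(max(abs(sma - pi / 4 * (5^4 - 3^4))) / (pi / 4 * (5^4 - 3^4)),
            0.02)
})

test_that("SMA has exact 180-degree redundancy and 90-degree conservation", {
  sec <- blob_section(seed = 2)
  sma <- sma_profile(sec)
  expect_equal(sma[37 + 1], sma[217 + 1])
  expect_equal(sma, sma[((0:359 + 180) %% 360) + 1])
  tot <- sma[1:180] + sma[91:270]
  expect_lt(diff(range(tot)) / mean(tot), 1e-9)
})

test_that("rotation formula equals brute-force pixel summation at every angle", {
  sec <- blob_section(seed = 7)
  ctr <- section_centroid(sec)
  sma <- sma_profile(sec, ctr)
  a <- sec$pixel_mm
  idx <- which(sec$mask, arr.ind = TRUE)
  x <- (idx[, 1] - 0.5) * a - ctr[1]
  y <- (idx[, 2] - 0.5) * a - ctr[2]
  for (th_deg in c(0, 13, 37, 90, 144, 271)) {
    th <- th_deg * pi / 180
    # perpendicular distance to an axis through the centroid at angle th
    d <- -x * sin(th) + y * cos(th)
    brute <- sum(d^2 * a^2) + nrow(idx) * a^4 / 12
    expect_lt(abs(sma[th_deg + 1] - brute) / brute, 1e-9)
  }
})

test_that("SMA extrema equal the moment-tensor eigenvalues", {
  for (seed in c(3, 8)) {
    sec <- blob_section(seed = seed)
    mom <- raw_moments(sec)
    sma <- sma_from_moments(mom, seq(0, 179.75, by = 0.25))
    ev <- eigen(matrix(c(mom$Ixx, -mom$Ixy, -mom$Ixy, mom$Iyy), 2, 2),
                symmetric = TRUE)$values
    spread <- max(ev) - min(ev)
    expect_lt(abs(max(sma) - max(ev)), 1e-4 * spread + 1e-12)
    expect_lt(abs(min(sma) - min(ev)), 1e-4 * spread + 1e-12)
  }
})

test_that("rotating a section by 90 degrees permutes profiles by 90 columns", {
  sec <- blob_section(seed = 5)
  # pad to square and rotate CCW: (x, y) -> (-y, x)
  m <- sec$mask
  n <- max(dim(m))
  sq <- matrix(FALSE, n, n)
  sq[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  rot <- t(sq[n:1, , drop = FALSE])      # (x, y) -> (y, -x): 90 deg clockwise
  s1 <- structure(list(mask = sq, pixel_mm = 0.1), class = "cross_section")
  s2 <- structure(list(mask = rot, pixel_mm = 0.1), class = "cross_section")
  t1 <- thickness_profile(radial_radii(s1))
  t2 <- thickness_profile(radial_radii(s2))
  expect_equal(t2, t1[((0:359 + 90) %% 360) + 1], tolerance = 1e-8)
})
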