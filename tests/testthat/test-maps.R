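test_that("standardization arithmetic and scaling behave as defined", {
  expect_equal(standardize_cbt(2, 60), 2 / 60)
  expect_equal(standardize_cbt(0, 60), 0)
  expect_equal(standardize_sma(427.3, 50, 60), 427.3 / 3000)
  expect_equal(standardize_sma(100, 80, 60), standardize_sma(100, 40, 60) / 2)
  expect_error(standardize_cbt(2, 0))
  expect_error(standardize_sma(1, -5, 60))
})

test_that("standardization uses group- and sex-specific mean masses", {
  meta <- data.frame(group = c("g", "g", "g"), sex = c("M", "M", "F"),
                     mass_kg = c(50, 60, 40))
  expect_equal(standardization_mass(meta), c(55, 55, 40))
})

test_that("body mass resolves directly or via regression, with clear errors", {
  expect_equal(body_mass_estimate(list(mass_kg = 48.5)), 48.5)
  cf <- list(M = c(a = 2, b = 1.5))
  expect_equal(body_mass_estimate(list(femoral_head_mm = 44, sex = "M"), cf),
               2 + 1.5 * 44)
  expect_error(body_mass_estimate(list(femoral_head_mm = 44, sex = "F"), cf),
               "coefficients")
  expect_error(body_mass_estimate(list(sex = "M")), "mass_kg")
})

test_that("consensus maps are pixelwise means and linear", {
  m1 <- matrix(runif(17 * 360), 17, 360)
  m2 <- matrix(runif(17 * 360), 17, 360)
  expect_equal(unclass(consensus_map(list(m1))), m1, ignore_attr = TRUE)
  expect_equal(unclass(consensus_map(list(m1, m1))), m1, ignore_attr = TRUE)
  expect_equal(unclass(consensus_map(list(m1, m2))), (m1 + m2) / 2,
               ignore_attr = TRUE)
})

test_that("CV maps use the n-1 sd, are scale invariant and zero for clones", {
  m <- matrix(runif(17 * 360, 1, 2), 17, 360)
  expect_true(all(cv_map(list(m, m, m)) == 0))
  # pixelwise {x, 3x}: sd = sqrt(2) x, mean = 2x -> CV = sqrt(2)/2
  expect_equal(unclass(cv_map(list(m, 3 * m))),
               matrix(sqrt(2) / 2, 17, 360), ignore_attr = TRUE)
  maps <- list(m, 1.4 * m, 0.8 * m)
  expect_equal(unclass(cv_map(maps)),
               unclass(cv_map(lapply(maps, `*`, 7.3))), tolerance = 1e-12)
  # direct-formula oracle at one pixel
  vals <- vapply(maps, `[`, numeric(1), 5, 100)
  expect_equal(cv_map(maps)[5, 100], stats::sd(vals) / mean(vals))
  expect_error(cv_map(list(m)), "at least 2")
})

test_that("color scaling modes share or separate anchors as requested", {
  g <- list(a = matrix(1:6, 2, 3), b = matrix(4:9, 2, 3))
  inter <- color_scale(g, "interspecific")
  expect_equal(inter$a, c(1, 9))
  expect_equal(inter$a, inter$b)
  intra <- color_scale(g, "intraspecific")
  expect_equal(intra$a, c(1, 6))
  expect_equal(intra$b, c(4, 9))
  # a single group makes the two modes coincide
  expect_equal(color_scale(g["a"], "interspecific"),
               color_scale(g["a"], "intraspecific"))
  expect_warning(color_scale(list(z = matrix(1, 2, 2)), "cv"), "degenerate")
})

test_that("rendering upsamples for display but never alters the data", {
  m <- matrix(runif(17 * 360, 0.02, 0.08), 17, 360)
  r <- render_map(m, anchors = c(0.02, 0.08), upsample = 4L)
  expect_equal(dim(r$rgb)[1:2], c(17 * 4, 360 * 4))
  expect_gte(dim(r$rgb)[1], nrow(m))
  expect_gte(dim(r$rgb)[2], ncol(m))
  expect_identical(r$data, m)
  expect_warning(render_map(matrix(1, 3, 4), anchors = c(1, 1)), "degenerate")
})

test_that("morphometric maps validate shape, finiteness and property", {
  vol <- generate_phantom(small_phantom_spec(L = 20, voxel = 0.25))
  pr <- measure_individual(vol)
  mp <- morphometric_map(pr, "CBT", group = "A")
  expect_equal(dim(mp), c(17, 360))
  expect_true(all(is.finite(mp)))
  expect_equal(attr(mp, "property"), "CBT")
  sm <- morphometric_map(pr, "SMA", mass_kg = 50)
  # sSMA inherits the 180-degree column redundancy
  expect_equal(unclass(sm)[, 1:180], unclass(sm)[, 181:360],
               ignore_attr = TRUE)
  expect_error(morphometric_map(pr, "SMA"), "mass_kg")
})

test_that("map CSV export round trips", {
  vol <- generate_phantom(small_phantom_spec(L = 20, voxel = 0.25))
  mp <- morphometric_map(measure_individual(vol), "CBT")
  p <- file.path(withr::local_tempdir(), "m.csv")
  export_map_csv(mp, p)
  back <- as.matrix(utils::read.csv(p, row.names = 1))
  expect_equal(unname(back), unclass(mp), ignore_attr = TRUE,
               tolerance = 1e-12)
})
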