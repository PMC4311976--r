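test_that("penalty matrix is a cylinder-grid Laplacian (null space, roughness)", {
  Om <- penalty_matrix(17, 360)
  p <- 17 * 360
  expect_equal(dim(Om), c(p, p))
  expect_lt(max(abs(Om %*% rep(1, p))), 1e-12)          # constant in null space
  expect_true(Matrix::isSymmetric(Om))
  # a one-pixel spike is rougher than a smooth ramp of equal norm
  spike <- numeric(p); spike[2000] <- 1
  ramp <- as.vector(matrix(rep(seq(0, 1, length.out = 17), 360), 17, 360))
  ramp <- ramp / sqrt(sum(ramp^2))
  expect_gt(as.numeric(spike %*% Om %*% spike),
            as.numeric(ramp %*% Om %*% ramp))
})

test_that("penalty quadratic form equals the brute-force neighbour-difference sum", {
  nr <- 3L; nc <- 4L
  Om <- penalty_matrix(nr, nc)
  withr::with_seed(2, x <- rnorm(nr * nc))
  xm <- matrix(x, nr, nc)
  brute <- 0
  for (r in 1:(nr - 1)) for (cc in 1:nc)
    brute <- brute + (xm[r + 1, cc] - xm[r, cc])^2
  for (r in 1:nr) for (cc in 1:nc)
    brute <- brute + (xm[r, cc %% nc + 1] - xm[r, cc])^2   # wrapped columns
  expect_equal(as.numeric(x %*% Om %*% x), brute, tolerance = 1e-12)
})

test_that("train/test split gives 12 per group and the 2/2/3 remainder", {
  labels <- rep(c("A", "B", "C"), times = c(14, 14, 15))
  sp <- split_train_test(labels, 12, seed = 3)
  expect_length(sp$train, 36)
  expect_length(sp$test, 7)
  expect_equal(as.integer(table(labels[sp$train])), c(12L, 12L, 12L))
  expect_equal(as.integer(table(labels[sp$test])), c(2L, 2L, 3L))
  expect_identical(sp, split_train_test(labels, 12, seed = 3))
  expect_error(split_train_test(rep(c("A", "B"), times = c(11, 14)), 12),
               "at least 12")
})

test_that("stratified folds partition the training set, one member per group", {
  labels <- factor(rep(c("A", "B", "C"), each = 12))
  withr::with_seed(1, folds <- make_cv_folds(labels, 12))
  expect_equal(sort(unique(folds)), 1:12)
  for (f in 1:12) {
    expect_length(which(folds == f), 3)
    expect_equal(sort(as.character(labels[folds == f])), c("A", "B", "C"))
  }
  expect_error(make_cv_folds(factor(rep("A", 11)), 12), "exactly 12")
})

test_that("a separable construction is fit with zero training errors", {
  withr::with_seed(4, {
    n <- 10; p <- 17 * 360
    X <- matrix(rnorm(2 * n * p, 0, 0.01), 2 * n, p)
    X[1:n, 500] <- X[1:n, 500] + 1          # one-pixel group difference
    labels <- rep(c("u", "v"), each = n)
    Om <- penalty_matrix(17, 360)
    fit <- fit_pda(X, labels, lambda = 1e-4, Omega = Om)
    expect_equal(fit$train_misclass, 0L)
    expect_equal(ncol(fit$coefficients), 1L)   # 2 groups -> 1 discriminant
    # duplicating every row leaves the discriminant direction unchanged
    fit2 <- fit_pda(rbind(X, X), rep(labels, 2), lambda = 1e-4, Omega = Om)
    cosang <- abs(sum(fit$coefficients * fit2$coefficients)) /
      sqrt(sum(fit$coefficients^2) * sum(fit2$coefficients^2))
    expect_gt(cosang, 1 - 1e-6)
  })
})

test_that("with lambda ridge, the fit matches a penalized LDA oracle", {
  withr::with_seed(7, {
    n <- 15; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    labels <- factor(rep(c("a", "b", "c"), each = 5))
    X[labels == "b", 3] <- X[labels == "b", 3] + 2
    X[labels == "c", 7] <- X[labels == "c", 7] - 2
    lam <- 0.5
    fit <- fit_pda(X, labels, lam, Omega = Matrix::Diagonal(p),
                   grid = c(3, 4))
    # oracle: eigenvectors of solve(W + c I) %*% B with 1/n covariances and
    # c = (lambda + eps) / n
    Xc <- sweep(X, 2, colMeans(X))
    W <- matrix(0, p, p); Bm <- matrix(0, p, p)
    for (g in levels(labels)) {
      Xg <- Xc[labels == g, , drop = FALSE]
      mg <- colMeans(Xg)
      W <- W + crossprod(sweep(Xg, 2, mg))
      Bm <- Bm + nrow(Xg) * tcrossprod(mg)
    }
    W <- W / n; Bm <- Bm / n
    E <- eigen(solve(W + (lam + fit$eps) / n * diag(p)) %*% Bm)
    for (d in 1:2) {
      v <- Re(E$vectors[, d]); b <- fit$coefficients[, d]
      expect_gt(abs(sum(v * b)) / sqrt(sum(v^2) * sum(b^2)), 1 - 1e-6)
    }
  })
})

test_that("df is monotone in lambda, bounded by n-1, and tends to 1", {
  withr::with_seed(5, {
    nr <- 5L; nc <- 12L; p <- nr * nc; n <- 9
    X <- matrix(rnorm(n * p), n, p)
    Om <- penalty_matrix(nr, nc)
    lams <- 10^seq(-4, 8, length.out = 12)
    dfs <- vapply(lams, function(l) effective_df(l, Om, X), numeric(1))
    expect_true(all(diff(dfs) <= 1e-8))
    expect_lte(dfs[1], n - 1 + 1e-6)
    # as lambda grows, df approaches dim(null(Omega)) = 1
    expect_lt(abs(dfs[length(dfs)] - 1), 0.05)
  })
})

test_that("df matches a dense eigendecomposition oracle on a toy grid", {
  withr::with_seed(6, {
    nr <- 3L; nc <- 4L; p <- nr * nc; n <- 8
    X <- matrix(rnorm(n * p), n, p)
    Om <- as.matrix(penalty_matrix(nr, nc))
    for (lam in c(0.01, 1, 50)) {
      Xc <- sweep(X, 2, colMeans(X))
      eps <- 1e-8 * sum(Xc^2) / p
      S <- Xc %*% solve(crossprod(Xc) + lam * Om + eps * diag(p)) %*% t(Xc)
      expect_equal(effective_df(lam, penalty_matrix(nr, nc), X),
                   sum(diag(S)), tolerance = 1e-8)
    }
  })
})

test_that("lambda selection picks the lowest admissible df on separable data", {
  coh <- synthetic_map_cohort(n_per_group = 12, noise_sd = 0.001,
                              patch_amp = 0.02, seed = 8)
  des <- map_design(coh$maps, coh$labels)
  Om <- penalty_matrix(17, 360)
  grid <- c(0.01, 1, 100)
  sel <- select_lambda(des$X, des$labels, Omega = Om, lambda_grid = grid,
                       n_folds = 12, repeats = 5, seed = 2)
  expect_true(all(sel$table$mean_err[sel$admissible] <=
                    min(sel$table$upper) + 1e-12))
  expect_equal(sel$lambda, max(grid[sel$admissible]))
  expect_equal(sel$df, min(sel$table$df[sel$admissible]))
  # a single-lambda grid returns that lambda
  s1 <- select_lambda(des$X, des$labels, Omega = Om, lambda_grid = 0.5,
                      n_folds = 12, repeats = 2, seed = 2)
  expect_equal(s1$lambda, 0.5)
  expect_warning(
    select_lambda(des$X, des$labels, Omega = Om, lambda_grid = 0.5,
                  n_folds = 12, repeats = 1, seed = 2),
    "degenerate")
})

test_that("projection is consistent with training centroids and global shifts", {
  coh <- synthetic_map_cohort(seed = 9)
  des <- map_design(coh$maps, coh$labels)
  fit <- fit_pda(des$X, des$labels, lambda = 1)
  sc <- project_pda(fit, des$X)
  expect_equal(unname(sc), unname(fit$train_scores), tolerance = 1e-6)
  for (g in seq_along(fit$levels))
    expect_equal(colMeans(sc[des$labels == fit$levels[g], , drop = FALSE]),
                 unname(fit$centroids[g, ]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  # adding the same constant map to every observation changes nothing
  fit2 <- fit_pda(des$X + 5, des$labels, lambda = 1)
  expect_equal(fit2$train_scores, fit$train_scores, tolerance = 1e-6)
  # classification of a centroid-like training row is its own label
  cl <- classify_pda(fit, des$X, truth = des$labels)
  expect_equal(cl$n_misclassified, 0L)
})

test_that("discriminants are orthogonal in the penalized metric", {
  withr::with_seed(10, {
    n <- 15; nr <- 4L; nc <- 10L; p <- nr * nc
    X <- matrix(rnorm(n * p, 0, 0.1), n, p)
    labels <- rep(c("a", "b", "c"), each = 5)
    X[labels == "b", 5] <- X[labels == "b", 5] + 1
    X[labels == "c", 25] <- X[labels == "c", 25] + 1
    Om <- penalty_matrix(nr, nc)
    lam <- 0.3
    fit <- fit_pda(X, labels, lam, Omega = Om, grid = c(nr, nc))
    Xc <- sweep(X, 2, colMeans(X))
    Mfull <- crossprod(Xc) + lam * as.matrix(Om) + fit$eps * diag(p)
    b1 <- fit$coefficients[, 1]; b2 <- fit$coefficients[, 2]
    cross <- abs(b1 %*% Mfull %*% b2)
    scale <- sqrt((b1 %*% Mfull %*% b1) * (b2 %*% Mfull %*% b2))
    expect_lt(cross / scale, 1e-6)
  })
})

test_that("loading maps reshape losslessly and localize a planted patch", {
  # thick-dorsal difference: the dorsal quadrant (30-150 deg) of the mid and
  # distal shaft is thicker in group g2
  coh <- synthetic_map_cohort(n_per_group = 10, noise_sd = 0.003,
                              patch_amp = 0.006, seed = 11,
                              patch_rows = 5:14, patch_cols = 31:150)
  des <- map_design(coh$maps, coh$labels)
  fit <- fit_pda(des$X, des$labels, lambda = 0.05)
  lm1 <- loading_map(fit, 1)
  expect_equal(as.vector(lm1$map), unname(fit$coefficients[, 1]))
  expect_equal(dim(lm1$map), c(17, 360))
  expect_equal(dim(lm1$boundary), c(17, 360))
  # orient so the patch-enriched group scores higher, then the half-maximum
  # region of the loading overlaps the planted patch
  s <- sign(fit$centroids[match("g2", fit$levels), 1] -
              fit$centroids[match("g1", fit$levels), 1])
  L <- s * lm1$map
  expect_gt(iou(L >= 0.5 * max(L), coh$patch), 0.5)
})

test_that("a lambda-to-infinity fit flattens loadings toward the null space", {
  coh <- synthetic_map_cohort(n_per_group = 6, seed = 12)
  des <- map_design(coh$maps, coh$labels)
  fit <- fit_pda(des$X, des$labels, lambda = 1e9)
  b <- fit$coefficients[, 1]
  expect_lt(stats::sd(b) / (abs(mean(b)) + 1e-300), 0.05)
  df_inf <- effective_df(1e9, penalty_matrix(17, 360), des$X)
  expect_lt(df_inf, 1.2)
})

test_that("models serialize to plain files and restore", {
  coh <- synthetic_map_cohort(n_per_group = 6, seed = 13)
  des <- map_design(coh$maps, coh$labels)
  fit <- fit_pda(des$X, des$labels, lambda = 1)
  d <- withr::local_tempdir()
  save_pda_model(fit, d)
  back <- load_pda_model(d)
  expect_equal(unname(back$coefficients), unname(fit$coefficients),
               tolerance = 1e-8)
  expect_equal(back$levels, fit$levels)
  expect_equal(back$lambda, fit$lambda)
  cl1 <- classify_pda(fit, des$X)
  cl2 <- classify_pda(back, des$X)
  expect_equal(as.character(cl1$labels), as.character(cl2$labels))
})
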