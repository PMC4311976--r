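#' Design matrix from morphometric maps
#'
#' Flattens a list of equally-shaped maps into an n x (rows*cols) matrix,
#' one row per individual, using column-major raster order (section index
#' fastest), the same ordering used by [penalty_matrix()] and
#' [loading_map()].
#'
#' @param maps list of map matrices (e.g. 17 x 360).
#' @param labels group label per map.
#' @return list with `X`, `labels` (factor) and `grid` (c(rows, cols)).
#' @export
map_design <- function(maps, labels) {
  d <- check_map_list(maps)
  stopifnot(length(maps) == length(labels))
  X <- do.call(rbind, lapply(maps, function(m) as.vector(unclass(m))))
  if (!all(is.finite(X))) stop("maps contain missing pixels")
  list(X = X, labels = factor(labels), grid = d)
}

#' Train/test split with a fixed per-group training count
#'
#' @param labels group label per individual.
#' @param per_group_train training individuals per group (default 12).
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return list with integer vectors `train` and `test`.
#' @export
split_train_test <- function(labels, per_group_train = 12L, seed = 1L) {
  labels <- factor(labels)
  ns <- table(labels)
  if (any(ns < per_group_train))
    stop(sprintf("every group needs at least %d members", per_group_train))
  train <- withr::with_seed(seed, {
    unlist(lapply(levels(labels), function(g) {
      ids <- which(labels == g)
      sort(ids[sample.int(length(ids), per_group_train)])
    }))
  })
  list(train = sort(train), test = setdiff(seq_along(labels), train))
}

#' Stratified cross-validation folds (one member per group per fold)
#'
#' Partitions the training rows into `n_folds` folds, each containing
#' exactly one member of every group, so every fold is a miniature of the
#' full design.  Requires each group to have exactly `n_folds` training
#' members.
#'
#' @param labels training labels.
#' @param n_folds number of folds (default 12).
#' @return integer vector of fold ids (1..n_folds) per training row.
#' @export
make_cv_folds <- function(labels, n_folds = 12L) {
  labels <- factor(labels)
  ns <- table(labels)
  if (!all(ns == n_folds))
    stop(sprintf("stratified folds need exactly %d members per group", n_folds))
  folds <- integer(length(labels))
  for (g in levels(labels))
    folds[labels == g] <- sample.int(n_folds)
  folds
}

#' Roughness penalty matrix for the cylindrical map grid
#'
#' The graph Laplacian `t(D) %*% D` of first differences on the rows x cols
#' grid, with wrap-around adjacency in the column (degree) dimension and no
#' wrap in the row (section) dimension.  Symmetric positive semidefinite;
#' the constant map spans its null space.  Pixel ordering is column-major
#' (matches [map_design()]).
#'
#' @param n_row,n_col grid dimensions (default 17 x 360).
#' @param wrap_cols wrap adjacency in the column dimension (default TRUE).
#' @return sparse symmetric `Matrix` of size (n_row*n_col)^2.
#' @export
penalty_matrix <- function(n_row = 17L, n_col = 360L, wrap_cols = TRUE) {
  id <- function(r, c) r + n_row * (c - 1L)
  rr <- seq_len(n_row)
  cc <- seq_len(n_col)
  # vertical edges (within a column of the grid; section direction)
  vi <- id(rep(rr[-n_row], n_col), rep(cc, each = n_row - 1L))
  vj <- id(rep(rr[-1L], n_col), rep(cc, each = n_row - 1L))
  # horizontal edges (angle direction), wrapped
  cnext <- if (wrap_cols) c(cc[-1L], 1L) else cc[-1L]
  cthis <- if (wrap_cols) cc else cc[-n_col]
  hi <- id(rep(rr, length(cthis)), rep(cthis, each = n_row))
  hj <- id(rep(rr, length(cnext)), rep(cnext, each = n_row))
  p <- n_row * n_col
  A <- Matrix::sparseMatrix(i = c(vi, hi), j = c(vj, hj), x = 1,
                            dims = c(p, p), symmetric = FALSE)
  A <- A + Matrix::t(A)
  A@x <- pmin(A@x, 1)
  Matrix::Diagonal(p, Matrix::rowSums(A)) - A
}

# lambda*Omega + eps*I with a sparse Cholesky factorization.  For extreme
# lambda the floating-point sum can be numerically semidefinite; the ridge
# is then bumped by the minimal power of ten that restores definiteness.
penalized_metric <- function(lambda, Omega, eps) {
  p <- nrow(Omega)
  eps0 <- if (eps > 0) eps else 1e-14 * max(lambda * mean(Matrix::diag(Omega)), 1)
  for (k in 0:10) {
    M <- lambda * Omega + Matrix::Diagonal(p, eps0 * 10^k)
    ch <- tryCatch(
      suppressWarnings(Matrix::Cholesky(methods::as(M, "symmetricMatrix"),
                                        LDL = FALSE, perm = TRUE)),
      error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("penalized metric is numerically singular; use lambda > 0 or a positive ridge")
}

ridge_eps <- function(Xc, eps_scale) eps_scale * sum(Xc^2) / ncol(Xc)

# Gram-level penalized optimal scoring.  G is the m x m Gram matrix
# t(Xc %*% solve(M) %*% t(Xc)) of the centered training design in the
# penalized metric; Y the class indicator matrix.  Returns scores scaled to
# unit pooled within-class sd, centroids, and the weight vector C such that
# coefficients = V %*% C for V = solve(M, t(Xc)).
pda_core <- function(G, Y) {
  m <- nrow(G)
  K <- ncol(Y)
  IG <- diag(m) + G
  Yhat <- G %*% solve(IG, Y)
  dn <- colSums(Y)
  Dm <- 1 / sqrt(dn)
  Tm <- (t(Y) %*% Yhat) * outer(Dm, Dm)
  Tm <- (Tm + t(Tm)) / 2
  eig <- eigen(Tm, symmetric = TRUE)
  ndisc <- K - 1L
  theta <- eig$vectors[, seq_len(ndisc), drop = FALSE] * Dm
  alpha2 <- eig$values[seq_len(ndisc)]
  C <- solve(IG, Y %*% theta)
  scores <- G %*% C
  cls <- max.col(Y, ties.method = "first")
  scl <- numeric(ndisc)
  for (d in seq_len(ndisc)) {
    cm <- tapply(scores[, d], cls, mean)
    wss <- sum((scores[, d] - cm[cls])^2)
    s <- sqrt(wss / max(1, m - K))
    scl[d] <- if (s > 1e-10) 1 / s else 1 / max(sqrt(sum(scores[, d]^2)), 1e-10)
  }
  scores <- sweep(scores, 2, scl, `*`)
  C <- sweep(C, 2, scl, `*`)
  cen <- vapply(seq_len(K), function(g)
    colMeans(scores[cls == g, , drop = FALSE]), numeric(ndisc))
  if (is.null(dim(cen))) cen <- matrix(cen, 1L, K)
  centroids <- t(cen)
  list(theta = theta, alpha2 = alpha2, C = C, scores = scores,
       centroids = centroids)
}

#' Fit a penalized discriminant analysis
#'
#' Penalized optimal scoring (the penalized form of linear discriminant
#' analysis for many correlated predictors and few samples): class
#' indicators are regressed on the centered design under the quadratic
#' roughness penalty `lambda * Omega` (plus a tiny ridge for
#' invertibility), optimal scores are extracted by an eigen decomposition,
#' and up to (groups - 1) discriminant functions are returned, ordered by
#' decreasing discriminatory eigenvalue.  Discriminant variates are scaled
#' to unit pooled within-class standard deviation, so nearest-centroid
#' classification in discriminant space is Mahalanobis-like.
#'
#' @param X n x p design (rows = flattened maps; see [map_design()]).
#' @param labels group label per row.
#' @param lambda roughness penalty weight (>= 0).
#' @param Omega penalty matrix (default [penalty_matrix()] sized to `grid`).
#' @param grid map grid dimensions c(rows, cols).
#' @param eps_scale ridge jitter relative to the design scale (default
#'   1e-8); the actual ridge is `eps_scale * sum(Xc^2) / p`.
#' @return a `pda_model`: coefficients (p x ndisc), centroids, training
#'   scores and labels, effective degrees of freedom `df`, eigenvalues
#'   `alpha2`, `lambda`, `eps`, `xbar`, `grid`, training misclassification
#'   count.
#' @export
fit_pda <- function(X, labels, lambda, Omega = NULL, grid = c(17L, 360L),
                    eps_scale = 1e-8) {
  labels <- factor(labels)
  n <- nrow(X)
  p <- ncol(X)
  K <- nlevels(labels)
  stopifnot(n >= K, lambda >= 0)
  if (is.null(Omega)) Omega <- penalty_matrix(grid[1], grid[2])
  stopifnot(nrow(Omega) == p)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  eps <- ridge_eps(Xc, eps_scale)
  if (lambda == 0 && eps <= 0 && p > n)
    stop("singular system: with p > n use lambda > 0 (or a positive ridge)")
  ch <- penalized_metric(lambda, Omega, eps)
  V <- as.matrix(Matrix::solve(ch, t(Xc)))
  A <- Xc %*% V
  A <- (A + t(A)) / 2
  Y <- stats::model.matrix(~ labels - 1)
  core <- pda_core(A, Y)
  beta <- V %*% core$C
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  df <- sum(pmax(ev, 0) / (1 + pmax(ev, 0)))
  scores <- core$scores
  pred <- classify_scores(scores, core$centroids, levels(labels))
  model <- structure(
    list(coefficients = beta, centroids = core$centroids,
         levels = levels(labels), theta = core$theta, alpha2 = core$alpha2,
         lambda = lambda, eps = eps, xbar = xbar, grid = grid, df = df,
         train_scores = scores, train_labels = labels, train_pred = pred,
         train_misclass = sum(pred != labels)),
    class = "pda_model")
  model
}

#' @export
print.pda_model <- function(x, ...) {
  cat(sprintf(
    "<pda_model> %d groups, %d discriminant function(s), lambda = %.4g, df = %.2f\n",
    length(x$levels), ncol(x$coefficients), x$lambda, x$df))
  cat(sprintf("  training misclassifications: %d / %d\n",
              x$train_misclass, nrow(x$train_scores)))
  invisible(x)
}

classify_scores <- function(scores, centroids, levels) {
  d2 <- vapply(seq_len(nrow(centroids)), function(g)
    rowSums(sweep(scores, 2, centroids[g, ])^2), numeric(nrow(scores)))
  if (nrow(scores) == 1) d2 <- matrix(d2, nrow = 1)
  # ties broken deterministically by group order
  factor(levels[max.col(-d2, ties.method = "first")], levels = levels)
}

#' Project observations into discriminant space
#'
#' @param model a fitted `pda_model`.
#' @param X matrix of flattened maps (same column order as training).
#' @return n x ndisc matrix of discriminant scores (PDF1, PDF2, ...).
#' @export
project_pda <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(X, 2, model$xbar) %*% model$coefficients
}

#' Classify observations by nearest group centroid
#'
#' @inheritParams project_pda
#' @param truth optional true labels; if given, misclassification count is
#'   returned.
#' @return list with `labels` (factor), `scores`, and (if `truth` given)
#'   `n_misclassified`.
#' @export
classify_pda <- function(model, X, truth = NULL) {
  scores <- project_pda(model, X)
  labels <- classify_scores(scores, model$centroids, model$levels)
  out <- list(labels = labels, scores = scores)
  if (!is.null(truth))
    out$n_misclassified <- sum(labels != factor(truth, levels = model$levels))
  out
}

#' Effective degrees of freedom of the penalized fit
#'
#' The trace of the penalized smoother
#' `Xc (Xc'Xc + lambda Omega + eps I)^-1 Xc'` on the (centered) training
#' design, computed as `sum(a / (1 + a))` over the eigenvalues `a` of the
#' penalized-metric Gram matrix.  Continuous and monotone non-increasing in
#' lambda; tends to the dimension of the penalty null space as lambda grows.
#'
#' @inheritParams fit_pda
#' @return effective degrees of freedom (scalar).
#' @export
effective_df <- function(lambda, Omega, X, eps_scale = 1e-8) {
  Xc <- sweep(X, 2, colMeans(X))
  eps <- ridge_eps(Xc, eps_scale)
  ch <- penalized_metric(lambda, Omega, eps)
  A <- Xc %*% as.matrix(Matrix::solve(ch, t(Xc)))
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(pmax(ev, 0) / (1 + pmax(ev, 0)))
}

# double-centered Gram of a training subset, plus centered test-vs-train
# rows, all derived from the raw (uncentered) Gram matrix
center_gram <- function(G_raw, tr, te = integer(0)) {
  A <- G_raw[tr, tr, drop = FALSE]
  colm <- colMeans(A)
  grand <- mean(A)
  Gc <- sweep(sweep(A, 2, colm), 1, colm) + grand
  Gt <- NULL
  if (length(te)) {
    B <- G_raw[te, tr, drop = FALSE]
    Gt <- sweep(B - rowMeans(B), 2, colm) + grand
  }
  list(train = (Gc + t(Gc)) / 2, test = Gt)
}

#' Select the roughness penalty by repeated stratified cross-validation
#'
#' For every lambda on the grid, estimates the expected test error by
#' repeated stratified k-fold cross-validation (each fold holds out one
#' member per group).  Across the repeat means an approximate 95%
#' prediction band (mean +/- t-quantile * sd) is formed; all lambdas whose
#' mean error does not exceed the minimum observed upper band limit are
#' admissible, and among these the one with the lowest effective degrees of
#' freedom (i.e. the largest lambda) is chosen.
#'
#' @inheritParams fit_pda
#' @param lambda_grid penalty grid; default 25 log-spaced values scaled to
#'   the design/penalty magnitude.
#' @param n_folds folds per run (default 12).
#' @param repeats cross-validation repeats (default 100).
#' @param seed seed governing fold assignment across repeats.
#' @param conf band coverage (default 0.95).
#' @return list with `lambda` (chosen), `df` (at the chosen lambda),
#'   `table` (per-lambda df, mean error, sd, upper band), `admissible`
#'   (logical), `repeats`, `n_folds`, `seed`.
#' @export
select_lambda <- function(X, labels, Omega = NULL, grid = c(17L, 360L),
                          lambda_grid = NULL, n_folds = 12L, repeats = 100L,
                          seed = 1L, conf = 0.95, eps_scale = 1e-8) {
  labels <- factor(labels)
  n <- nrow(X)
  K <- nlevels(labels)
  if (is.null(Omega)) Omega <- penalty_matrix(grid[1], grid[2])
  Xc <- sweep(X, 2, colMeans(X))
  if (is.null(lambda_grid)) {
    base <- sum(Xc^2) / ncol(Xc) / mean(Matrix::diag(Omega))
    lambda_grid <- base * 10^seq(-3, 6, length.out = 25)
  }
  lambda_grid <- sort(lambda_grid)
  eps <- ridge_eps(Xc, eps_scale)
  Y <- stats::model.matrix(~ labels - 1)
  nl <- length(lambda_grid)

  G_raw <- vector("list", nl)
  dfs <- numeric(nl)
  for (l in seq_len(nl)) {
    ch <- penalized_metric(lambda_grid[l], Omega, eps)
    G <- X %*% as.matrix(Matrix::solve(ch, t(X)))
    G_raw[[l]] <- (G + t(G)) / 2
    cg <- center_gram(G_raw[[l]], seq_len(n))
    ev <- eigen(cg$train, symmetric = TRUE, only.values = TRUE)$values
    dfs[l] <- sum(pmax(ev, 0) / (1 + pmax(ev, 0)))
  }

  errs <- withr::with_seed(seed, {
    e <- matrix(NA_real_, repeats, nl)
    for (r in seq_len(repeats)) {
      folds <- make_cv_folds(labels, n_folds)
      for (l in seq_len(nl)) {
        wrong <- 0L
        for (f in seq_len(n_folds)) {
          te <- which(folds == f)
          tr <- which(folds != f)
          cg <- center_gram(G_raw[[l]], tr, te)
          core <- pda_core(cg$train, Y[tr, , drop = FALSE])
          ts <- cg$test %*% core$C
          pred <- classify_scores(ts, core$centroids, levels(labels))
          wrong <- wrong + sum(pred != labels[te])
        }
        e[r, l] <- wrong / n
      }
    }
    e
  })

  mean_err <- colMeans(errs)
  sd_err <- apply(errs, 2, stats::sd)
  if (repeats > 1) {
    tq <- stats::qt(1 - (1 - conf) / 2, repeats - 1)
    upper <- mean_err + tq * sd_err
  } else {
    warning("a single repeat gives a degenerate prediction band")
    upper <- mean_err
  }
  if (all(mean_err >= 1 - 1e-12)) {
    warning("all lambda values misclassify everything; selection impossible")
    return(list(lambda = NA_real_, df = NA_real_,
                table = data.frame(lambda = lambda_grid, df = dfs,
                                   mean_err = mean_err, sd = sd_err,
                                   upper = upper),
                admissible = rep(FALSE, nl), repeats = repeats,
                n_folds = n_folds, seed = seed))
  }
  admissible <- mean_err <= min(upper) + 1e-12
  cand <- which(admissible)
  chosen <- cand[order(dfs[cand], -lambda_grid[cand])][1]
  list(lambda = lambda_grid[chosen], df = dfs[chosen],
       table = data.frame(lambda = lambda_grid, df = dfs,
                          mean_err = mean_err, sd = sd_err, upper = upper),
       admissible = admissible, repeats = repeats, n_folds = n_folds,
       seed = seed)
}

#' Loading map of a discriminant function
#'
#' Reshapes the requested discriminant's coefficients back to the map grid
#' (lossless), with the sign map and the zero-crossing boundary (pixels
#' whose sign differs from the next pixel up or around).
#'
#' A positive loading at a pixel means a larger property value there
#' increases the score on that discriminant axis.
#'
#' @param model a `pda_model`.
#' @param which discriminant index (1 = PDF1, 2 = PDF2).
#' @return list with `map` (rows x cols signed matrix), `sign` and
#'   `boundary` (logical matrix).
#' @export
loading_map <- function(model, which = 1L) {
  stopifnot(which >= 1, which <= ncol(model$coefficients))
  m <- matrix(model$coefficients[, which], model$grid[1], model$grid[2])
  s <- sign(m)
  right <- cbind(s[, -1], s[, 1])           # wrap in angle
  up <- rbind(s[-1, ], s[nrow(s), ])
  list(map = m, sign = s, boundary = (s != right) | (s != up))
}

#' Serialize / restore a fitted PDA model as plain files
#'
#' Coefficients, centroids and training scores are written as CSV; scalar
#' metadata as JSON.
#'
#' @param model a `pda_model`.
#' @param dir output directory (created if needed).
#' @return `dir` (for `save_pda_model`) / the model (for `load_pda_model`).
#' @export
save_pda_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model$coefficients, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(model$centroids, file.path(dir, "centroids.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(xbar = model$xbar), file.path(dir, "xbar.csv"),
                   row.names = FALSE)
  meta <- list(levels = model$levels, lambda = model$lambda, eps = model$eps,
               grid = model$grid, df = model$df, alpha2 = model$alpha2,
               train_misclass = model$train_misclass)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_pda_model
#' @export
load_pda_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  model <- list(
    coefficients = as.matrix(utils::read.csv(file.path(dir, "coefficients.csv"))),
    centroids = as.matrix(utils::read.csv(file.path(dir, "centroids.csv"))),
    xbar = utils::read.csv(file.path(dir, "xbar.csv"))$xbar,
    levels = meta$levels, lambda = meta$lambda, eps = meta$eps,
    grid = meta$grid, df = meta$df, alpha2 = meta$alpha2,
    train_misclass = meta$train_misclass)
  class(model) <- "pda_model"
  model
}
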