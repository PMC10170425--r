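#' Network estimation configuration
#'
#' Settings for the node-wise LASSO regressions that build a cross-lagged
#' panel network.
#'
#' @param n_lambda length of the per-node penalty grid (default 100,
#'   log-spaced from `lambda_max` down to `lambda_min_ratio * lambda_max`).
#' @param lambda_min_ratio smallest grid penalty relative to `lambda_max`
#'   (default 0.001).
#' @param lambda_grid optional explicit strictly descending penalty grid,
#'   overriding the automatic per-node grid.
#' @param cv_folds number of cross-validation folds (default 10, >= 2).
#' @param cv_seed integer seed entering the fold-assignment hash.
#' @param lambda_rule `"min"` (CV-MSE minimizer, default) or `"1se"`
#'   (largest penalty within one standard error of the minimum).
#' @param standardize z-score predictors and outcomes before fitting
#'   (default `TRUE`; edge weights are then standardized coefficients).
#' @param display_threshold default threshold for
#'   [apply_display_threshold()] (display only, default 0.05).
#' @param tol coordinate-descent convergence tolerance (default 1e-7).
#' @param max_sweeps coordinate-descent sweep cap (default 1e5).
#' @return list of class `estimation_config`.
#' @export
estimation_config <- function(n_lambda = 100, lambda_min_ratio = 0.001,
                              lambda_grid = NULL, cv_folds = 10, cv_seed = 1,
                              lambda_rule = c("min", "1se"),
                              standardize = TRUE, display_threshold = 0.05,
                              tol = 1e-7, max_sweeps = 1e5) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(cv_folds >= 2, n_lambda >= 2, lambda_min_ratio > 0,
            lambda_min_ratio < 1, display_threshold >= 0)
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) || is.unsorted(rev(lambda_grid), strictly = TRUE))
      stop("lambda_grid must be strictly descending and positive")
  }
  structure(list(n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 lambda_grid = lambda_grid,
                 cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed),
                 lambda_rule = lambda_rule,
                 standardize = isTRUE(standardize),
                 display_threshold = display_threshold,
                 tol = tol, max_sweeps = as.integer(max_sweeps)),
            class = "estimation_config")
}

#' Smallest penalty with an all-zero LASSO solution
#'
#' `max_i |<x_i, y>| / n` for centered `X` and `y`: at any penalty at or
#' above this value the LASSO coefficient vector is identically zero.
#'
#' @param X centered predictor matrix.
#' @param y centered outcome vector.
#' @return non-negative scalar; 0 with a warning when `y` has zero variance.
#' @export
lambda_max <- function(X, y) {
  if (sd(y) == 0) {
    warning("outcome has zero variance; lambda_max is 0")
    return(0)
  }
  max(abs(crossprod(X, y))) / nrow(X)
}

#' LASSO fit at fixed penalties (no cross-validation)
#'
#' Minimizes `(1/(2n)) ||y - X b||^2 + lambda ||b||_1` by cyclic coordinate
#' descent with warm starts along the (descending) penalty vector. `X` and
#' `y` are centered internally; no intercept is returned (it is zero after
#' centering).
#'
#' @param X predictor matrix.
#' @param y outcome vector.
#' @param lambda penalty or descending penalty vector (`0` allowed: ordinary
#'   least squares).
#' @param tol,max_sweeps convergence controls.
#' @return coefficient matrix `ncol(X)` x `length(lambda)` (a plain vector
#'   when one penalty is given).
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-9, max_sweeps = 1e5) {
  X <- sweep(as.matrix(X), 2, colMeans(X), "-")
  y <- y - mean(y)
  beta <- lasso_path_gram(crossprod(X), drop(crossprod(X, y)), nrow(X),
                          as.numeric(lambda), tol, as.integer(max_sweeps))
  rownames(beta) <- colnames(X)
  if (length(lambda) == 1) drop(beta) else beta
}

# Subject-order-invariant fold assignment: subjects are ranked by the
# FNV-1a hash of "<id>#<cv_seed>" and folds are filled round-robin in hash
# order, so folds are balanced and identical for any row permutation.
# Duplicate ids (bootstrap resamples) land in the same fold.
assign_folds <- function(subject_ids, k, cv_seed) {
  u <- unique(subject_ids)
  h <- fnv1a_hash(paste0(u, "#", cv_seed))
  ord <- order(h, u)                     # u breaks ties deterministically
  fold_of <- integer(length(u))
  fold_of[ord] <- rep_len(seq_len(k), length(u))
  fold_of[match(subject_ids, u)]
}

# Cross-validated lasso for one outcome on precomputed per-fold Gram pieces.
# G_folds/c_folds/yty_folds/n_folds: lists over folds of crossprod(Xf),
# crossprod(Xf, yf), sum(yf^2), nrow(Xf); all data centered (and scaled if
# requested) on the full estimation sample beforehand.
cv_lasso_gram <- function(G_folds, c_folds, yty_folds, n_folds, config) {
  k <- length(G_folds)
  G <- Reduce(`+`, G_folds)
  cvec <- Reduce(`+`, c_folds)
  n <- sum(n_folds)
  lam_max <- max(abs(cvec)) / n
  if (lam_max <= 0) {
    grid <- config$lambda_grid %||% c(1, 0.5)
  } else {
    grid <- config$lambda_grid %||%
      exp(seq(log(lam_max), log(lam_max * config$lambda_min_ratio),
              length.out = config$n_lambda))
  }
  nl <- length(grid)
  mse <- matrix(NA_real_, k, nl)
  for (f in seq_len(k)) {
    if (n_folds[f] == 0) next
    Gt <- G - G_folds[[f]]
    ct <- cvec - c_folds[[f]]
    path <- lasso_path_gram(Gt, ct, n - n_folds[f], grid,
                            config$tol, config$max_sweeps)
    # held-out MSE via Gram identity: (y'y - 2 b'X'y + b'X'Xb)/n_f
    quad <- colSums(path * (G_folds[[f]] %*% path))
    lin <- drop(crossprod(c_folds[[f]], path))
    mse[f, ] <- (yty_folds[f] - 2 * lin + quad) / n_folds[f]
  }
  used <- n_folds > 0
  mse_u <- mse[used, , drop = FALSE]
  cv_mean <- colSums(mse_u * n_folds[used]) / n
  cv_se <- col_sds(mse_u) / sqrt(sum(used))
  i_min <- which.min(cv_mean)
  i_sel <- if (config$lambda_rule == "1se") {
    min(which(cv_mean <= cv_mean[i_min] + cv_se[i_min]))
  } else i_min
  path_full <- lasso_path_gram(G, cvec, n, grid, config$tol,
                               config$max_sweeps)
  list(coef = path_full[, i_sel], lambda = grid[i_sel], lambda_grid = grid,
       cv_mse = cv_mean, cv_se = cv_se, path = path_full)
}

#' Node-wise LASSO regression with cross-validated penalty
#'
#' Fits one outcome (an item at wave t+1) on the wave-t predictor matrix by
#' coordinate-descent LASSO along a log-spaced penalty grid, selecting the
#' penalty by k-fold cross-validated prediction MSE. Fold assignment hashes
#' the subject identifiers, so results do not depend on row order.
#'
#' @param X predictor matrix (subjects x items at wave t).
#' @param y outcome vector (one item at wave t+1).
#' @param config an [estimation_config].
#' @param subjects subject identifiers for fold hashing (defaults to row
#'   numbers).
#' @return list with `coef` (on the standardized scale when
#'   `config$standardize`), `lambda`, `lambda_grid`, `cv_mse`, `cv_se`,
#'   `path`.
#' @export
fit_node_lasso <- function(X, y, config = estimation_config(),
                           subjects = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in estimation sample")
  if (n <= ncol(X))
    warning("fewer subjects than predictors; estimates will be unstable")
  if (n < config$cv_folds) stop("fewer subjects than cross-validation folds")
  if (is.null(subjects)) subjects <- as.character(seq_len(n))
  if (config$standardize) {
    if (any(col_sds(X) == 0)) stop("zero-variance predictor column")
    if (sd(y) == 0) stop("zero-variance outcome")
    X <- scale_cols(X)
    y <- drop(scale(y))
  } else {
    X <- sweep(X, 2, colMeans(X), "-")
    y <- y - mean(y)
  }
  folds <- assign_folds(subjects, config$cv_folds, config$cv_seed)
  G_folds <- list(); c_folds <- list()
  yty_folds <- numeric(config$cv_folds); n_folds <- integer(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    idx <- folds == f
    Xf <- X[idx, , drop = FALSE]
    G_folds[[f]] <- crossprod(Xf)
    c_folds[[f]] <- drop(crossprod(Xf, y[idx]))
    yty_folds[f] <- sum(y[idx]^2)
    n_folds[f] <- sum(idx)
  }
  out <- cv_lasso_gram(G_folds, c_folds, yty_folds, n_folds, config)
  names(out$coef) <- colnames(X)
  out
}
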