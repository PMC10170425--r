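test_that("lambda_max is the smallest all-zero penalty", {
  set.seed(1)
  n <- 200
  # outcome orthogonal to every column
  X <- cbind(rep(c(1, -1), n / 2), rep(c(1, 1, -1, -1), n / 4))
  y <- rep(c(1, -1, -1, 1), n / 4)
  expect_equal(lambda_max(X, y), 0)
  # single standardized predictor with correlation 0.6
  x1 <- rnorm(n)
  y2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  x1s <- drop(scale(x1)) * sqrt(n / (n - 1))   # unit 1/n-norm
  y2s <- drop(scale(y2)) * sqrt(n / (n - 1))
  lm1 <- lambda_max(matrix(x1s), y2s)
  expect_equal(lm1, abs(sum(x1s * y2s)) / n, tolerance = 1e-12)
  expect_equal(lm1, abs(cor(x1, y2)), tolerance = 1e-12)
  # defining property: fit at lambda_max is identically zero
  X3 <- matrix(rnorm(n * 6), n, 6)
  y3 <- X3 %*% runif(6, -1, 1) + rnorm(n)
  lmax <- lambda_max(sweep(X3, 2, colMeans(X3)), y3 - mean(y3))
  expect_true(all(lasso_fit(X3, y3, lmax) == 0))
  expect_true(any(lasso_fit(X3, y3, lmax * 0.99) != 0))
  expect_warning(lambda_max(X3, rep(2, n)), "zero variance")
})

test_that("lambda = 0 reproduces the normal-equation OLS solution", {
  set.seed(2)
  for (r in 1:5) {
    X <- matrix(rnorm(50 * 5), 50, 5)
    y <- X %*% runif(5, -1, 1) + rnorm(50)
    Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
    ols <- drop(solve(crossprod(Xc), crossprod(Xc, yc)))
    expect_equal(unname(lasso_fit(X, y, 0)), ols, tolerance = 1e-6)
  }
})

test_that("orthonormal design reduces to the soft-threshold closed form", {
  set.seed(3)
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * 8), n, 8)))
  Q <- sweep(Q, 2, colMeans(Q))               # recenter; near-orthogonal
  X <- qr.Q(qr(Q)) * sqrt(n)                  # columns with X'X = n I
  b_true <- c(2, -1.5, 1, -0.5, 0.25, -0.1, 0.05, 0)
  y <- X %*% b_true + rnorm(n, sd = 0.3)
  y <- y - mean(y)
  ols <- drop(crossprod(X, y)) / n
  for (lam in c(0.01, 0.1, 0.3, 0.8)) {
    b <- lasso_fit(X, y, lam)
    expect_equal(unname(b), sign(ols) * pmax(abs(ols) - lam, 0),
                 tolerance = 1e-8)
  }
})

test_that("fixed-penalty solutions beat perturbations and match ISTA", {
  set.seed(4)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- X %*% c(1, -0.5, 0, 0, 0.25) + rnorm(50)
  lam <- 0.2
  b <- lasso_fit(X, y, lam)
  f0 <- lasso_objective(X, y, b, lam)
  for (i in 1:2000) {
    pert <- b + rnorm(5, sd = sample(c(1e-4, 1e-2, 0.1), 1))
    expect_gte(lasso_objective(X, y, pert, lam), f0 - 1e-12)
  }
  b_ista <- ista_lasso(X, y, lam, iters = 20000)
  expect_lte(abs(f0 - lasso_objective(X, y, b_ista, lam)), 1e-6)
})

test_that("solutions agree with glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  n <- 500; p <- 13
  S <- matrix(0.4, p, p); diag(S) <- 1
  X <- MASS::mvrnorm(n, rep(0, p), S)
  y <- X %*% c(0.3, -0.2, rep(0, 10), 0.15) + rnorm(n)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  lmax <- lambda_max(Xc, yc)
  grid <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 30))
  mine <- lasso_fit(X, y, grid)
  ref <- as.matrix(coef(glmnet::glmnet(
    Xc, yc, lambda = grid, standardize = FALSE, intercept = FALSE,
    thresh = 1e-14)))[-1, ]
  expect_lt(max(abs(mine - ref)), 1e-5)
})

test_that("sparsity is monotone along every regularization path", {
  set.seed(6)
  for (r in 1:5) {
    X <- matrix(rnorm(120 * 10), 120, 10)
    y <- X %*% (rbinom(10, 1, 0.4) * runif(10, -1, 1)) + rnorm(120)
    Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
    lmax <- lambda_max(Xc, yc)
    grid <- exp(seq(log(lmax), log(lmax * 0.001), length.out = 60))
    path <- lasso_fit(X, y, grid)
    nz <- colSums(path != 0)
    expect_true(all(diff(nz) >= 0))
  }
})

test_that("cross-validated node fits are reproducible and order-invariant", {
  sm <- sim_medium()
  X <- wave_matrix(sm$data, "1")
  y <- wave_matrix(sm$data, "2")[, "depressed"]
  cfg <- estimation_config(cv_seed = 42)
  f1 <- fit_node_lasso(X, y, cfg, subjects = sm$data$subjects)
  f2 <- fit_node_lasso(X, y, cfg, subjects = sm$data$subjects)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$coef, f2$coef)
  perm <- sample(nrow(X))
  f3 <- fit_node_lasso(X[perm, ], y[perm], cfg,
                       subjects = sm$data$subjects[perm])
  expect_equal(f3$coef, f1$coef, tolerance = 1e-12)
  expect_identical(f3$lambda, f1$lambda)
  # different cv seed may move lambda but the machinery stays deterministic
  f4 <- fit_node_lasso(X, y, estimation_config(cv_seed = 43),
                       subjects = sm$data$subjects)
  expect_true(is.finite(f4$lambda))
})

test_that("the 1se rule never selects a smaller penalty than the minimum rule", {
  sm <- sim_medium()
  X <- wave_matrix(sm$data, "1")
  for (node in c("depressed", "confidence", "loneliness")) {
    y <- wave_matrix(sm$data, "2")[, node]
    fmin <- fit_node_lasso(X, y, estimation_config(lambda_rule = "min"),
                           subjects = sm$data$subjects)
    f1se <- fit_node_lasso(X, y, estimation_config(lambda_rule = "1se"),
                           subjects = sm$data$subjects)
    expect_gte(f1se$lambda, fmin$lambda)
  }
})

test_that("fold assignment is balanced, deterministic and id-driven", {
  ids <- sprintf("SUBJ%04d", 1:997)
  set.seed(10)
  perm <- sample(997)
  f1 <- clpnet:::assign_folds(ids, 10, 7)
  f2 <- clpnet:::assign_folds(ids[perm], 10, 7)
  expect_equal(sort(unique(f1)), 1:10)
  expect_true(max(table(f1)) - min(table(f1)) <= 1)
  # same subject keeps its fold regardless of row order
  expect_identical(f2, f1[perm])
  # duplicated ids (bootstrap resamples) share a fold
  f3 <- clpnet:::assign_folds(c("A", "B", "A", "A"), 3, 1)
  expect_true(all(f3[c(1, 3, 4)] == f3[1]))
  # a different seed reshuffles folds
  expect_false(identical(clpnet:::assign_folds(ids, 10, 8), f1))
})

test_that("estimation is equivariant to raw item rescaling when standardized", {
  sm <- sim_medium()
  X <- wave_matrix(sm$data, "1")
  Y <- wave_matrix(sm$data, "2")
  net1 <- clpn_fit(X, Y, estimation_config(cv_seed = 9),
                   subjects = sm$data$subjects)
  X10 <- X; X10[, 3] <- X10[, 3] * 10
  net2 <- clpn_fit(X10, Y, estimation_config(cv_seed = 9),
                   subjects = sm$data$subjects)
  expect_equal(net1$W, net2$W, tolerance = 1e-10)
})
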