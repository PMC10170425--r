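# Shared fixtures and a memo cache so expensive simulation studies are run
# once per test session and reused across test blocks.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small complete panel with known values: 4 subjects, 2 waves
toy_panel <- function() {
  schema <- default_item_schema()
  set.seed(99)
  arr <- array(NA_real_, c(4, 13, 2))
  for (i in 1:13) {
    lo <- schema$scale_min[i]; hi <- schema$scale_max[i]
    arr[, i, ] <- sample(lo:hi, 8, replace = TRUE)
  }
  panel_dataset(arr, paste0("P", 1:4), c("1", "2"), schema,
                aux = data.frame(subject = paste0("P", 1:4),
                                 sex = c(0, 1, 0, 1),
                                 ethnicity = c(0, 0, 1, 0),
                                 age = c(25, 40, 60, 75)))
}

# medium simulated panel + truth, shared by several estimation tests
sim_medium <- function() memo("sim_medium", {
  model <- default_true_model()
  list(model = model,
       data = simulate_panel(model, simulation_config(2000, 2, seed = 301)))
})

# 20-replicate recovery study at n = 4000 (shared by the parameter-recovery
# and hub-recovery acceptance checks)
recovery_study <- function() memo("recovery_study", {
  model <- default_true_model()
  off <- row(model$B) != col(model$B)
  strong <- off & abs(model$B) >= 0.15
  reps <- lapply(1:20, function(r) {
    d <- simulate_panel(model, simulation_config(4000, 2, seed = 1000 + r))
    net <- estimate_clpn(d, c("1", "2"))
    ei <- expected_influence(net)
    list(
      sign_rate = mean(sign(net$W[strong]) == sign(model$B[strong])),
      pearson = cor(model$B[off], net$W[off]),
      hub_rank = match("loneliness", ei$node[order(-ei$out_ei)])
    )
  })
  list(model = model,
       sign_rate = vapply(reps, `[[`, numeric(1), "sign_rate"),
       pearson = vapply(reps, `[[`, numeric(1), "pearson"),
       hub_rank = vapply(reps, `[[`, numeric(1), "hub_rank"))
})

# independent proximal-gradient (ISTA) lasso minimizer used as oracle
ista_lasso <- function(X, y, lambda, iters = 50000) {
  X <- sweep(X, 2, colMeans(X)); y <- y - mean(y)
  n <- nrow(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  b <- rep(0, ncol(X))
  step <- 1 / L
  for (i in seq_len(iters)) {
    g <- crossprod(X, X %*% b - y) / n
    u <- b - step * g
    b <- sign(u) * pmax(abs(u) - step * lambda, 0)
  }
  b
}

lasso_objective <- function(X, y, b, lambda) {
  X <- sweep(X, 2, colMeans(X)); y <- y - mean(y)
  sum((y - X %*% b)^2) / (2 * nrow(X)) + lambda * sum(abs(b))
}
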