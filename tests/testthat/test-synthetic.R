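test_that("identical seeds give identical datasets; different seeds differ", {
  model <- default_true_model()
  cfg <- simulation_config(200, 3, seed = 17)
  d1 <- simulate_panel(model, cfg)
  d2 <- simulate_panel(model, cfg)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$aux, d2$aux)
  expect_identical(d1$latent, d2$latent)
  d3 <- simulate_panel(model, simulation_config(200, 3, seed = 18))
  expect_false(identical(d1$responses, d3$responses))
})

test_that("degenerate model (B = 0, no noise, point-mass start) is constant", {
  schema <- default_item_schema()
  p <- 13
  thr <- lapply(seq_len(p), function(i) {
    k <- schema$scale_max[i] - schema$scale_min[i]   # cuts above 0
    seq(0.5, by = 1, length.out = k)
  })
  model <- true_model(B = matrix(0, p, p), innovation_sd = 0,
                      wave1_cov = matrix(0, p, p), thresholds = thr,
                      schema = schema)
  d <- simulate_panel(model, simulation_config(50, 3, seed = 1))
  for (i in seq_len(p))
    expect_true(all(d$responses[, i, ] == schema$scale_min[i]))
})

test_that("latent cross-lagged coefficient is recovered by OLS at large n", {
  p <- 13
  B <- matrix(0, p, p)
  B[2, 1] <- 0.5
  schema <- default_item_schema()
  thr <- lapply(seq_len(p), function(i)
    qnorm(seq_len(schema$scale_max[i] - schema$scale_min[i]) /
            (schema$scale_max[i] - schema$scale_min[i] + 1)))
  model <- true_model(B, innovation_sd = sqrt(1 - rowSums(B^2)),
                      wave1_cov = diag(p), thresholds = thr, schema = schema)
  d <- simulate_panel(model, simulation_config(50000, 2, seed = 5))
  z1 <- scale(d$latent[, , 1])
  y2 <- scale(d$latent[, 2, 2])
  b <- coef(lm.fit(cbind(1, z1), drop(y2)))[-1]
  expect_equal(unname(b[1]), 0.5, tolerance = 0.04)
  expect_true(all(abs(b[-1]) < 0.02))
})

test_that("model invariants are enforced", {
  p <- 13
  thr <- default_true_model()$thresholds
  expect_error(true_model(diag(1.2, p), 1, diag(p), thr), "spectral radius")
  bad_thr <- thr; bad_thr[[1]] <- c(1, 0.5, 2)
  expect_error(true_model(diag(0.3, p), 1, diag(p), bad_thr),
               "strictly increasing")
  short_thr <- thr; short_thr[[1]] <- c(0, 1)
  expect_error(true_model(diag(0.3, p), 1, diag(p), short_thr), "cut-points")
  expect_error(true_model(diag(0.3, p), 1, -diag(p), thr),
               "positive semi-definite")
})

test_that("default model has the designated hubs and stationary dynamics", {
  model <- default_true_model()
  expect_lt(max(abs(eigen(model$B, only.values = TRUE)$values)), 1)
  expect_true(all(diag(model$B) == 0.3))
  off <- model$B; diag(off) <- 0
  n_cross <- sum(off != 0)
  expect_gte(n_cross, 15)
  expect_lte(n_cross, 25)
  expect_true(all(abs(off[off != 0]) >= 0.10 - 1e-12))
  # brute-force true out-EI: loneliness strictly on top
  tei <- true_expected_influence(model)
  oracle_out <- vapply(seq_len(13), function(i) sum(off[-i, i]), numeric(1))
  expect_equal(tei$out_ei, oracle_out)
  expect_equal(tei$node[which.max(tei$out_ei)], "loneliness")
  # depressed collects the most incoming weight
  expect_equal(tei$node[which.max(tei$in_ei)], "depressed")
})

test_that("ordinal marginals match the threshold-implied probabilities", {
  model <- default_true_model()
  d <- simulate_panel(model, simulation_config(50000, 2, seed = 9))
  # wave-1 latents are exactly standard normal, so P(X = k) comes from the
  # normal CDF at the cut-points
  for (i in c(1, 11, 13)) {
    cuts <- model$thresholds[[i]]
    probs <- diff(c(0, pnorm(cuts), 1))
    lo <- model$schema$scale_min[i]
    emp <- tabulate(d$responses[, i, 1] - lo + 1, nbins = length(probs)) / 50000
    expect_equal(emp, probs, tolerance = 0.01)
  }
})

test_that("MAR dropout follows the logistic model on covariates", {
  model <- default_true_model()
  d <- memo("mar_base", simulate_panel(model, simulation_config(10000, 2, seed = 21)))
  # near -Inf intercept: no missingness
  none <- suppressMessages(apply_mar_missingness(
    d, c(intercept = -30, sex = 0, ethnicity = 0, age = 0), seed = 1))
  expect_false(anyNA(none$responses))
  # intercept-only at 0: dropout rate 1/2
  half <- suppressMessages(apply_mar_missingness(
    d, c(intercept = 0, sex = 0, ethnicity = 0, age = 0), seed = 1))
  rate <- mean(is.na(half$responses[, 1, 2]))
  expect_equal(rate, 0.5, tolerance = 0.02)
  # wave 1 is always observed; a dropped wave is missing wholesale
  expect_false(anyNA(half$responses[, , 1]))
  miss_rows <- is.na(half$responses[, 1, 2])
  expect_true(all(is.na(half$responses[miss_rows, , 2])))
  # a larger age coefficient strictly increases dropout among the old
  old <- d$aux$age >= 65
  rate_old <- function(b_age) {
    dd <- suppressMessages(apply_mar_missingness(
      d, c(intercept = -1, sex = 0, ethnicity = 0, age = b_age), seed = 3))
    mean(is.na(dd$responses[old, 1, 2]))
  }
  expect_gt(rate_old(1.0), rate_old(0.3) + 0.02)
})

test_that("item-level missingness mode leaves partial interviews", {
  model <- default_true_model()
  d <- simulate_panel(model, simulation_config(2000, 2, seed = 31))
  di <- suppressMessages(apply_mar_missingness(
    d, c(intercept = -2, sex = 0, ethnicity = 0, age = 0), seed = 4,
    level = "item"))
  m2 <- is.na(di$responses[, , 2])
  # some subjects have some but not all items missing
  per_subj <- rowSums(m2)
  expect_true(any(per_subj > 0 & per_subj < 13))
  expect_lt(abs(mean(m2) - plogis(-2)), 0.01)
})
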