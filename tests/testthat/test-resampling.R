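# small latent-scale problem shared by the bootstrap tests
boot_fixture <- function() memo("boot_fixture", {
  model <- default_true_model()
  d <- simulate_panel(model, simulation_config(600, 2, seed = 41))
  xy <- list(X = d$latent[, , 1], Y = d$latent[, , 2], subjects = d$subjects)
  bt <- suppressMessages(bootstrap_edges(xy, config = estimation_config(),
                                         n_boot = 120, seed = 43))
  list(model = model, xy = xy, bt = bt)
})

test_that("bootstrap is deterministic given its seed", {
  fx <- boot_fixture()
  b1 <- suppressMessages(suppressWarnings(
    bootstrap_edges(fx$xy, n_boot = 2, seed = 7, diff_tests = FALSE)))
  b2 <- suppressMessages(suppressWarnings(
    bootstrap_edges(fx$xy, n_boot = 2, seed = 7, diff_tests = FALSE)))
  expect_identical(b1$samples, b2$samples)
  b3 <- suppressMessages(suppressWarnings(
    bootstrap_edges(fx$xy, n_boot = 2, seed = 8, diff_tests = FALSE)))
  expect_false(identical(b1$samples, b3$samples))
})

test_that("percentile CIs match a sort-and-interpolate oracle", {
  fx <- boot_fixture()
  bt <- fx$bt
  # independent percentile oracle (type-7): on a stored bootstrap vector
  pct_oracle <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  cols <- sample(ncol(bt$samples), 12)
  for (k in cols) {
    expect_equal(bt$ci$lower[k], pct_oracle(bt$samples[, k], 0.025),
                 tolerance = 1e-12)
    expect_equal(bt$ci$upper[k], pct_oracle(bt$samples[, k], 0.975),
                 tolerance = 1e-12)
  }
  expect_true(all(bt$ci$lower <= bt$ci$upper))
  expect_true(all(is.finite(bt$ci$lower) & is.finite(bt$ci$upper)))
  # ten-value worked example
  v <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10)
  expect_equal(unname(quantile(v, 0.025)), pct_oracle(v, 0.025))
})

test_that("edge difference tests are symmetric and match the interval rule", {
  fx <- boot_fixture()
  bt <- fx$bt
  e_self <- "loneliness->depressed"
  expect_false(edge_difference_test(bt, e_self, e_self))
  # brute-force oracle over a sample of edge pairs
  set.seed(44)
  keys <- sample(colnames(bt$samples), 12)
  for (i in 1:6) {
    a <- keys[2 * i - 1]; b <- keys[2 * i]
    d <- bt$samples[, a] - bt$samples[, b]
    q <- unname(quantile(d, c(0.025, 0.975)))
    oracle <- q[1] > 0 || q[2] < 0
    expect_identical(edge_difference_test(bt, a, b), oracle)
    expect_identical(edge_difference_test(bt, b, a), oracle)
  }
  # edges whose bootstrap difference never changes sign are significant
  shifted <- bt
  shifted$samples[, keys[1]] <- abs(shifted$samples[, keys[2]]) + 1
  expect_true(edge_difference_test(shifted, keys[1], keys[2]))
  # vector form c(from, to) is accepted
  expect_identical(
    edge_difference_test(bt, c("loneliness", "depressed"),
                         c("worthless", "confidence")),
    edge_difference_test(bt, "loneliness->depressed",
                         "worthless->confidence"))
})

test_that("centrality difference tests mirror the edge machinery", {
  fx <- boot_fixture()
  bt <- fx$bt
  expect_false(centrality_difference_test(bt, "depressed", "depressed", "out"))
  nodes <- fx$bt$point$nodes
  for (i in 1:5) {
    a <- sample(nodes, 1); b <- sample(setdiff(nodes, a), 1)
    d <- bt$centrality_samples[, a, "in"] - bt$centrality_samples[, b, "in"]
    q <- unname(quantile(d, c(0.025, 0.975)))
    oracle <- q[1] > 0 || q[2] < 0
    expect_identical(centrality_difference_test(bt, a, b, "in"), oracle)
    expect_identical(centrality_difference_test(bt, b, a, "in"), oracle)
  }
  # matrices are symmetric with FALSE diagonal and agree with the tests
  M <- bt$centrality_diff_significant$out
  expect_true(isSymmetric(M))
  expect_false(any(diag(M)))
  expect_identical(M["loneliness", "happy"],
                   centrality_difference_test(bt, "loneliness", "happy", "out"))
  E <- bt$edge_diff_significant
  expect_true(isSymmetric(E))
  expect_false(any(diag(E)))
})

test_that("a dominant true out-hub is significant against every other node", {
  fx <- boot_fixture()
  bt <- fx$bt
  # loneliness' true out-EI exceeds all others by ~0.2+; at n=600 latent
  # scale with 120 bootstraps it should separate from most nodes
  others <- setdiff(bt$point$nodes, "loneliness")
  sig <- vapply(others, function(nd)
    centrality_difference_test(bt, "loneliness", nd, "out"), logical(1))
  expect_gt(mean(sig), 0.7)
})

test_that("case-drop stability yields a sane curve and CS-coefficient", {
  fx <- boot_fixture()
  st <- memo("stab_small", suppressMessages(casedrop_stability(
    fx$xy, config = estimation_config(), drop_grid = c(0.1, 0.3, 0.5),
    n_boot_per_level = 40, seed = 45)))
  expect_true(all(st$curve$mean_cor >= -1 & st$curve$mean_cor <= 1))
  expect_true(all(st$cs_coefficient %in% c(0, st$drop_grid)))
  # CS-coefficient from an independent scan over the stored correlations
  for (ix in c("out", "in")) {
    ok <- vapply(seq_along(st$drop_grid), function(l) {
      x <- st$correlations[l, , ix]
      mean(!is.na(x) & x >= 0.7) >= 0.95
    }, logical(1))
    cs_oracle <- 0
    for (l in seq_along(st$drop_grid)) {
      if (!all(ok[1:l])) break
      cs_oracle <- st$drop_grid[l]
    }
    expect_equal(unname(st$cs_coefficient[ix]), cs_oracle)
  }
})

test_that("a full-sample 'subsample' correlates perfectly with itself", {
  fx <- boot_fixture()
  full <- expected_influence(clpn_fit(fx$xy$X, fx$xy$Y,
                                      subjects = fx$xy$subjects))
  # drop proportion -> 0: the subsample estimate is the full estimate
  st0 <- suppressMessages(casedrop_stability(
    fx$xy, drop_grid = 1 / nrow(fx$xy$X), n_boot_per_level = 2, seed = 46))
  expect_gt(min(st0$correlations[1, , "out"]), 0.97)
})

test_that("bootstrap CI widths shrink with sample size", {
  model <- default_true_model()
  widths <- vapply(c(500, 4000), function(n) {
    d <- simulate_panel(model, simulation_config(n, 2, seed = 47))
    xy <- list(X = d$latent[, , 1], Y = d$latent[, , 2],
               subjects = d$subjects)
    bt <- suppressWarnings(suppressMessages(
      bootstrap_edges(xy, n_boot = 60, seed = 48, diff_tests = FALSE)))
    offd <- bt$ci$from != bt$ci$to
    stats::median(bt$ci$upper[offd] - bt$ci$lower[offd])
  }, numeric(1))
  expect_gt(widths[1], widths[2])
})
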