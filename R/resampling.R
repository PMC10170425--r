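#' Nonparametric bootstrap of network edge weights
#'
#' Resamples subjects with replacement, re-runs the full estimation
#' procedure per resample (penalties re-selected by cross-validation every
#' time, since fixing them would understate variability), and collects the
#' edge-weight and expected-influence bootstrap distributions. 95% CIs are
#' empirical 2.5/97.5 percentiles per edge. Resamples in which some item has
#' zero variance are redrawn (at most 10 attempts each, logged).
#'
#' Pairwise difference-test matrices at `alpha = 0.05` are attached:
#' `edge_diff_significant` over cross-lagged edge pairs and
#' `centrality_diff_significant` per index over node pairs; both symmetric
#' with a `FALSE` diagonal (see [edge_difference_test()]).
#'
#' @param data a [panel_dataset], or a list `list(X =, Y =, subjects =)` of
#'   matrices (e.g. latent simulation values).
#' @param wave_pair wave labels (ignored for matrix input).
#' @param config an [estimation_config].
#' @param n_boot number of bootstrap resamples (>= 100 recommended; a
#'   warning is given below 1000).
#' @param seed integer seed; determines all resamples.
#' @param diff_tests compute the pairwise difference matrices? (default
#'   `TRUE`; disable for speed in large simulation loops).
#' @return object of class `clpn_bootstrap`: `samples` (n_boot x edges
#'   matrix, columns `from->to`), `point` (the full-sample network), `ci`
#'   (per-edge data frame), `centrality_samples` (n_boot x nodes x 2),
#'   difference matrices, `n_boot`, `seed`, `n_redraws`.
#' @export
bootstrap_edges <- function(data, wave_pair = NULL,
                            config = estimation_config(), n_boot = 1000,
                            seed = 1, diff_tests = TRUE) {
  if (n_boot < 100) warning("n_boot below 100; intervals will be unreliable")
  else if (n_boot < 1000) message("note: n_boot below 1000")
  xy <- as_xy(data, wave_pair)
  point <- clpn_fit(xy$X, xy$Y, config, xy$subjects, xy$wave_pair)
  p <- length(point$nodes)
  edge_names <- paste0(rep(point$nodes, each = p), "->",
                       rep(point$nodes, times = p))
  set.seed(as.integer(seed))
  n <- nrow(xy$X)
  samples <- matrix(NA_real_, n_boot, p * p,
                    dimnames = list(NULL, edge_names))
  cent <- array(NA_real_, c(n_boot, p, 2),
                dimnames = list(NULL, point$nodes, c("out", "in")))
  n_redraws <- 0L
  for (b in seq_len(n_boot)) {
    net_b <- NULL
    for (attempt in seq_len(10)) {
      idx <- sample.int(n, n, replace = TRUE)
      net_b <- tryCatch(
        clpn_fit(xy$X[idx, , drop = FALSE], xy$Y[idx, , drop = FALSE],
                 config, xy$subjects[idx], xy$wave_pair),
        error = function(e) NULL)
      if (!is.null(net_b)) break
      n_redraws <- n_redraws + 1L
    }
    if (is.null(net_b))
      stop(sprintf("bootstrap resample %d failed after 10 redraws", b))
    samples[b, ] <- as.vector(net_b$W)     # column-major: (to, from) pairs
    ei <- expected_influence(net_b)
    cent[b, , 1] <- ei$out_ei
    cent[b, , 2] <- ei$in_ei
  }
  if (n_redraws > 0)
    message(sprintf("%d degenerate resamples redrawn", n_redraws))
  ci <- data.frame(
    from = rep(point$nodes, each = p),
    to = rep(point$nodes, times = p),
    point = as.vector(point$W),
    lower = apply(samples, 2, quantile, 0.025),
    upper = apply(samples, 2, quantile, 0.975),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- structure(
    list(samples = samples, point = point, ci = ci,
         centrality_samples = cent, n_boot = as.integer(n_boot),
         seed = as.integer(seed), n_redraws = n_redraws),
    class = "clpn_bootstrap")
  if (diff_tests) {
    out$edge_diff_significant <- edge_difference_matrix(out)
    out$centrality_diff_significant <- list(
      out = centrality_difference_matrix(out, "out"),
      "in" = centrality_difference_matrix(out, "in"))
  }
  out
}

#' @export
print.clpn_bootstrap <- function(x, ...) {
  cat(sprintf("clpn_bootstrap: %d resamples of a %d-node network (seed %d)\n",
              x$n_boot, length(x$point$nodes), x$seed))
  cat(sprintf("median 95%% CI width (cross-lagged edges): %.3f\n",
              stats::median((x$ci$upper - x$ci$lower)[x$ci$from != x$ci$to])))
  invisible(x)
}

# Accept a panel_dataset or a list(X, Y, subjects) and return the matrices.
as_xy <- function(data, wave_pair) {
  if (inherits(data, "panel_dataset")) {
    wave_pair <- as.character(wave_pair)
    X <- wave_matrix(data, wave_pair[1])
    Y <- wave_matrix(data, wave_pair[2])
    ok <- stats::complete.cases(X) & stats::complete.cases(Y)
    list(X = X[ok, , drop = FALSE], Y = Y[ok, , drop = FALSE],
         subjects = data$subjects[ok], wave_pair = wave_pair)
  } else if (is.list(data) && all(c("X", "Y") %in% names(data))) {
    n <- nrow(data$X)
    list(X = as.matrix(data$X), Y = as.matrix(data$Y),
         subjects = data$subjects %||% sprintf("R%07d", seq_len(n)),
         wave_pair = if (is.null(wave_pair)) c("t", "t+1") else wave_pair)
  } else stop("data must be a panel_dataset or list(X, Y, subjects)")
}

edge_key <- function(from, to) paste0(from, "->", to)

#' Bootstrap difference test between two edge weights
#'
#' The edges differ significantly when the central
#' `(alpha/2, 1 - alpha/2)` percentile interval of the bootstrap
#' distribution of their difference excludes zero. Symmetric in the two
#' edges; an edge compared with itself is never significant.
#'
#' @param result a `clpn_bootstrap`.
#' @param edge_a,edge_b edges as `"from->to"` strings or length-2
#'   `c(from, to)` vectors.
#' @param alpha test level (default 0.05).
#' @return logical flag.
#' @export
edge_difference_test <- function(result, edge_a, edge_b, alpha = 0.05) {
  key <- function(e) if (length(e) == 2) edge_key(e[1], e[2]) else e
  a <- key(edge_a); b <- key(edge_b)
  if (!all(c(a, b) %in% colnames(result$samples)))
    stop("unknown edge name")
  d <- result$samples[, a] - result$samples[, b]
  q <- quantile(d, c(alpha / 2, 1 - alpha / 2))
  unname(q[1] > 0 || q[2] < 0)
}

#' Bootstrap difference test between two nodes' expected influence
#'
#' As [edge_difference_test()], applied to the bootstrap distributions of
#' the expected-influence difference of two nodes (centrality recomputed in
#' every bootstrap network).
#'
#' @param result a `clpn_bootstrap`.
#' @param node_a,node_b node labels.
#' @param index `"out"` or `"in"`.
#' @param alpha test level (default 0.05).
#' @return logical flag.
#' @export
centrality_difference_test <- function(result, node_a, node_b,
                                       index = c("out", "in"),
                                       alpha = 0.05) {
  index <- match.arg(index)
  d <- result$centrality_samples[, node_a, index] -
    result$centrality_samples[, node_b, index]
  q <- quantile(d, c(alpha / 2, 1 - alpha / 2))
  unname(q[1] > 0 || q[2] < 0)
}

#' Pairwise edge difference-test matrix
#'
#' @param result a `clpn_bootstrap`.
#' @param alpha test level.
#' @param include_autoregressive include diagonal (autoregressive) edges?
#' @return symmetric logical matrix over edges, `FALSE` diagonal.
#' @export
edge_difference_matrix <- function(result, alpha = 0.05,
                                   include_autoregressive = FALSE) {
  keep <- if (include_autoregressive) colnames(result$samples) else {
    ar <- result$ci$from == result$ci$to
    colnames(result$samples)[!ar]
  }
  S <- result$samples[, keep, drop = FALSE]
  m <- length(keep)
  lo <- matrix(FALSE, m, m, dimnames = list(keep, keep))
  for (i in seq_len(m - 1)) {
    d <- S[, (i + 1):m, drop = FALSE] - S[, i]
    qs <- apply(d, 2, quantile, c(alpha / 2, 1 - alpha / 2))
    sig <- qs[1, ] > 0 | qs[2, ] < 0
    lo[i, (i + 1):m] <- sig
    lo[(i + 1):m, i] <- sig
  }
  lo
}

#' Pairwise centrality difference-test matrix
#'
#' @param result a `clpn_bootstrap`.
#' @param index `"out"` or `"in"`.
#' @param alpha test level.
#' @return symmetric logical matrix over nodes, `FALSE` diagonal.
#' @export
centrality_difference_matrix <- function(result, index = c("out", "in"),
                                         alpha = 0.05) {
  index <- match.arg(index)
  nodes <- dimnames(result$centrality_samples)[[2]]
  m <- length(nodes)
  out <- matrix(FALSE, m, m, dimnames = list(nodes, nodes))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      s <- centrality_difference_test(result, nodes[i], nodes[j], index,
                                      alpha)
      out[i, j] <- s; out[j, i] <- s
    }
  }
  out
}

#' Case-drop bootstrap stability of centrality
#'
#' For each drop proportion `p` on the grid, repeatedly retains a random
#' `(1-p)` fraction of subjects without replacement, re-estimates the
#' network, and correlates subset expected influence with the full-sample
#' values. The CS-coefficient per index is the largest `p` such that at
#' every `p' <= p` at least 95% of subsamples correlate >= 0.7 with the
#' full sample (0 when none does); degenerate correlations count as
#' failures.
#'
#' @param data a [panel_dataset] or `list(X, Y, subjects)`.
#' @param wave_pair wave labels (ignored for matrix input).
#' @param config an [estimation_config].
#' @param drop_grid drop proportions (default `seq(0.1, 0.7, 0.1)`).
#' @param n_boot_per_level subsamples per proportion (default 1000).
#' @param seed integer seed.
#' @param cor_threshold,coverage CS-coefficient rule constants
#'   (conventionally 0.7 and 0.95).
#' @return object of class `clpn_stability`: `correlations` (levels x
#'   subsamples x 2 array), `curve` (summary data frame), `cs_coefficient`
#'   (named vector, out/in), `drop_grid`, `seed`.
#' @export
casedrop_stability <- function(data, wave_pair = NULL,
                               config = estimation_config(),
                               drop_grid = seq(0.1, 0.7, by = 0.1),
                               n_boot_per_level = 1000, seed = 1,
                               cor_threshold = 0.7, coverage = 0.95) {
  xy <- as_xy(data, wave_pair)
  n <- nrow(xy$X)
  if (min(1 - drop_grid) * n < 50)
    warning("smallest retained fraction leaves fewer than 50 subjects")
  full <- expected_influence(clpn_fit(xy$X, xy$Y, config, xy$subjects,
                                      xy$wave_pair))
  set.seed(as.integer(seed))
  nl <- length(drop_grid)
  cors <- array(NA_real_, c(nl, n_boot_per_level, 2),
                dimnames = list(paste0("drop", drop_grid), NULL,
                                c("out", "in")))
  for (l in seq_len(nl)) {
    keep_n <- round((1 - drop_grid[l]) * n)
    for (b in seq_len(n_boot_per_level)) {
      idx <- sample.int(n, keep_n)
      ei <- tryCatch(
        expected_influence(clpn_fit(xy$X[idx, , drop = FALSE],
                                    xy$Y[idx, , drop = FALSE], config,
                                    xy$subjects[idx], xy$wave_pair)),
        error = function(e) NULL)
      if (is.null(ei)) next                 # failure stays NA
      if (sd(ei$out_ei) > 0 && sd(full$out_ei) > 0)
        cors[l, b, "out"] <- cor(ei$out_ei, full$out_ei)
      if (sd(ei$in_ei) > 0 && sd(full$in_ei) > 0)
        cors[l, b, "in"] <- cor(ei$in_ei, full$in_ei)
    }
  }
  cs_of <- function(index) {
    ok <- vapply(seq_len(nl), function(l) {
      mean(!is.na(cors[l, , index]) & cors[l, , index] >= cor_threshold)
    }, numeric(1))
    pass <- ok >= coverage
    run <- cumprod(pass) == 1                  # all p' <= p must pass
    if (any(run)) drop_grid[max(which(run))] else 0
  }
  curve <- do.call(rbind, lapply(c("out", "in"), function(ix) {
    data.frame(
      index = ix,
      drop = drop_grid,
      mean_cor = apply(cors[, , ix, drop = FALSE], 1, mean, na.rm = TRUE),
      prop_above = vapply(seq_len(nl), function(l)
        mean(!is.na(cors[l, , ix]) & cors[l, , ix] >= cor_threshold),
        numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  structure(
    list(correlations = cors, curve = curve,
         cs_coefficient = c(out = cs_of("out"), "in" = cs_of("in")),
         drop_grid = drop_grid, seed = as.integer(seed),
         cor_threshold = cor_threshold, coverage = coverage),
    class = "clpn_stability")
}

#' @export
print.clpn_stability <- function(x, ...) {
  cat(sprintf("clpn_stability: CS-coefficient out = %.1f, in = %.1f\n",
              x$cs_coefficient["out"], x$cs_coefficient["in"]))
  invisible(x)
}
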