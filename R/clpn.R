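#' Cross-lagged panel network object
#'
#' @param W weight matrix with `W[j, i]` the standardized coefficient of
#'   predictor `i` (wave t) in the regression of outcome `j` (wave t+1);
#'   diagonal entries are the autoregressive paths.
#' @param lambdas selected penalty per outcome node.
#' @param wave_pair length-2 character vector `(t, t+1)`.
#' @param n_used number of subjects entering estimation.
#' @param config the [estimation_config] used.
#' @return object of class `clpn_network`.
#' @export
clpn_network <- function(W, lambdas, wave_pair, n_used, config) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W), all(is.finite(W)))
  structure(list(nodes = rownames(W), W = W, lambdas = lambdas,
                 wave_pair = as.character(wave_pair),
                 n_used = as.integer(n_used), config = config),
            class = "clpn_network")
}

#' @export
print.clpn_network <- function(x, ...) {
  cat(sprintf(
    "clpn_network: %d nodes, wave %s -> %s, n = %d, %d non-zero cross-lagged edges\n",
    length(x$nodes), x$wave_pair[1], x$wave_pair[2], x$n_used,
    count_nonzero_edges(x, include_autoregressive = FALSE)))
  invisible(x)
}

#' Estimate a cross-lagged panel network from matrices
#'
#' Matrix-level core of [estimate_clpn()]: takes the wave-t predictor matrix
#' and the wave-(t+1) outcome matrix directly (e.g. the latent continuous
#' values of a simulation), z-standardizes all columns on the estimation
#' sample, and runs one cross-validated LASSO regression per outcome.
#' Rows are sorted by subject identifier first, making the result invariant
#' to row permutations.
#'
#' @param X numeric matrix, subjects x items at wave t.
#' @param Y numeric matrix, subjects x items at wave t+1 (same columns).
#' @param config an [estimation_config].
#' @param subjects subject identifiers (default row numbers).
#' @param wave_pair labels stored on the result.
#' @return a [clpn_network].
#' @export
clpn_fit <- function(X, Y, config = estimation_config(), subjects = NULL,
                     wave_pair = c("t", "t+1")) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == ncol(Y))
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  if (is.null(subjects)) subjects <- sprintf("R%07d", seq_len(n))
  subjects <- as.character(subjects)
  ord <- order(subjects)
  X <- X[ord, , drop = FALSE]; Y <- Y[ord, , drop = FALSE]
  subjects <- subjects[ord]
  if (n < 50) warning("fewer than 50 subjects; network will be unstable")
  sds <- c(col_sds(X), col_sds(Y))
  if (any(sds == 0)) {
    bad <- rep(colnames(X), 2)[which(sds == 0)[1]]
    stop(sprintf("zero variance for item '%s' in the estimation sample", bad))
  }
  if (config$standardize) {
    X <- scale_cols(X)
    Y <- scale_cols(Y)
  } else {
    X <- sweep(X, 2, colMeans(X), "-")
    Y <- sweep(Y, 2, colMeans(Y), "-")
  }
  folds <- assign_folds(subjects, config$cv_folds, config$cv_seed)
  G_folds <- list(); C_folds <- list()
  YtY_folds <- matrix(0, config$cv_folds, p)
  n_folds <- integer(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    idx <- folds == f
    Xf <- X[idx, , drop = FALSE]
    G_folds[[f]] <- crossprod(Xf)
    C_folds[[f]] <- crossprod(Xf, Y[idx, , drop = FALSE])
    YtY_folds[f, ] <- colSums(Y[idx, , drop = FALSE]^2)
    n_folds[f] <- sum(idx)
  }
  W <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  lambdas <- numeric(p)
  for (j in seq_len(p)) {
    fit <- cv_lasso_gram(
      G_folds,
      lapply(C_folds, function(C) C[, j]),
      YtY_folds[, j], n_folds, config)
    W[j, ] <- fit$coef
    lambdas[j] <- fit$lambda
  }
  names(lambdas) <- colnames(X)
  clpn_network(W, lambdas, wave_pair, n, config)
}

#' Estimate a cross-lagged panel network for one wave pair
#'
#' Runs 13 (one per item) cross-validated LASSO regressions of each
#' wave-(t+1) item on all wave-t items, so every cross-lagged path adjusts
#' for the outcome's autoregressive effect and all other symptoms. Subjects
#' with any missing response at either wave are excluded (estimation is
#' meant to follow imputation).
#'
#' @param data a [panel_dataset].
#' @param wave_pair length-2 vector of wave labels `(t, t+1)`.
#' @param config an [estimation_config].
#' @return a [clpn_network].
#' @export
estimate_clpn <- function(data, wave_pair, config = estimation_config()) {
  wave_pair <- as.character(wave_pair)
  X <- wave_matrix(data, wave_pair[1])
  Y <- wave_matrix(data, wave_pair[2])
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  clpn_fit(X[ok, , drop = FALSE], Y[ok, , drop = FALSE], config,
           subjects = data$subjects[ok], wave_pair = wave_pair)
}

#' Count non-zero edges of a network
#'
#' @param net a [clpn_network].
#' @param include_autoregressive count the diagonal too? (default `FALSE`:
#'   cross-lagged edges only).
#' @return integer count of entries with `|W| > 0`.
#' @export
count_nonzero_edges <- function(net, include_autoregressive = FALSE) {
  W <- net$W
  if (!include_autoregressive) diag(W) <- 0
  sum(W != 0)
}

#' Display-thresholded copy of a network
#'
#' Zeroes all entries with `|W| < threshold` (strict inequality: an entry
#' exactly at the threshold is retained) in a copy used for display and
#' reporting only; estimation results, centrality and bootstrap always use
#' the unthresholded weights.
#'
#' @param net a [clpn_network].
#' @param threshold non-negative display threshold (default from the
#'   network's config, conventionally 0.05).
#' @return a [clpn_network] copy.
#' @export
apply_display_threshold <- function(net,
                                    threshold = net$config$display_threshold) {
  stopifnot(threshold >= 0)
  net$W[abs(net$W) < threshold] <- 0
  net
}

#' Edge list of a network
#'
#' @param net a [clpn_network].
#' @return data frame `from`, `to`, `weight`, `wave_t`, `wave_t1`,
#'   `autoregressive` covering every ordered node pair (zeros included).
#' @export
edge_list <- function(net) {
  p <- length(net$nodes)
  data.frame(
    from = rep(net$nodes, each = p),
    to = rep(net$nodes, times = p),
    weight = as.vector(net$W),   # column-major: W[, i] = edges out of node i
    wave_t = net$wave_pair[1],
    wave_t1 = net$wave_pair[2],
    autoregressive = rep(net$nodes, each = p) == rep(net$nodes, times = p),
    stringsAsFactors = FALSE
  )
}

#' Serialize a network to JSON
#'
#' @param net a [clpn_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    nodes = net$nodes,
    W = net$W,
    lambdas = as.list(net$lambdas),
    wave_pair = net$wave_pair,
    n_used = net$n_used,
    config = net$config[c("n_lambda", "lambda_min_ratio", "cv_folds",
                          "cv_seed", "lambda_rule", "standardize",
                          "display_threshold")]
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
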