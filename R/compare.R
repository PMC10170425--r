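#' Compare cross-lagged panel networks
#'
#' For every pair of networks: the Pearson correlation of the vectorized
#' cross-lagged (off-diagonal) edge weights — structural zeros included by
#' default — and the Pearson correlations of in- and out-expected-influence.
#' Per network: non-zero cross-lagged edge count (and the count including
#' autoregressive paths) and the strongest-edge table.
#'
#' @param nets named list of [clpn_network]s over identical node sets.
#' @param nonzero_union_only correlate only the edges non-zero in at least
#'   one of the two networks (default `FALSE`: all off-diagonal entries).
#' @param k number of strongest edges tabulated per network (default 5).
#' @return list of class `clpn_comparison` with data frames `pairs`,
#'   `counts`, and a named list `top_edges`.
#' @export
compare_networks <- function(nets, nonzero_union_only = FALSE, k = 5) {
  stopifnot(length(nets) >= 1)
  if (is.null(names(nets)))
    names(nets) <- vapply(nets, function(n) paste(n$wave_pair, collapse = "-"),
                          character(1))
  nodes <- nets[[1]]$nodes
  for (net in nets)
    if (!identical(net$nodes, nodes)) stop("networks have different node sets")
  offdiag <- function(W) W[row(W) != col(W)]
  eis <- lapply(nets, expected_influence)
  pairs <- NULL
  if (length(nets) >= 2) {
    combos <- utils::combn(names(nets), 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(c0) {
      a <- combos[1, c0]; b <- combos[2, c0]
      wa <- offdiag(nets[[a]]$W); wb <- offdiag(nets[[b]]$W)
      if (nonzero_union_only) {
        keep <- wa != 0 | wb != 0
        wa <- wa[keep]; wb <- wb[keep]
      }
      data.frame(
        net_a = a, net_b = b,
        edge_r = if (sd(wa) > 0 && sd(wb) > 0) cor(wa, wb) else NA_real_,
        out_ei_r = centrality_correlation(eis[[a]], eis[[b]], "out"),
        in_ei_r = centrality_correlation(eis[[a]], eis[[b]], "in"),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }))
  }
  counts <- data.frame(
    network = names(nets),
    nonzero_cross_lagged = vapply(nets, count_nonzero_edges, integer(1)),
    nonzero_incl_autoregressive = vapply(nets, count_nonzero_edges,
                                         integer(1),
                                         include_autoregressive = TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(pairs = pairs, counts = counts,
                 top_edges = lapply(nets, top_edges, k = k)),
            class = "clpn_comparison")
}

#' @export
print.clpn_comparison <- function(x, ...) {
  cat("Non-zero edges per network:\n"); print(x$counts)
  if (!is.null(x$pairs)) {
    cat("\nPairwise correlations:\n"); print(x$pairs, digits = 3)
  }
  invisible(x)
}

#' Strongest edges of a network
#'
#' Edges ranked by absolute weight (descending); ties broken by
#' `(from, to)` lexicographic order for determinism. Zero-weight edges are
#' never listed, so fewer than `k` rows may be returned.
#'
#' @param net a [clpn_network].
#' @param k number of edges (default 5).
#' @param exclude_autoregressive drop diagonal paths (default `TRUE`).
#' @return data frame `from`, `to`, `weight`, `rank`.
#' @export
top_edges <- function(net, k = 5, exclude_autoregressive = TRUE) {
  stopifnot(k >= 1)
  el <- edge_list(net)
  if (exclude_autoregressive) el <- el[!el$autoregressive, , drop = FALSE]
  el <- el[el$weight != 0, , drop = FALSE]
  el <- el[order(-abs(el$weight), el$from, el$to), , drop = FALSE]
  el <- utils::head(el, k)
  out <- data.frame(from = el$from, to = el$to, weight = el$weight,
                    rank = seq_len(nrow(el)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
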