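#' Expected-influence centrality of a directed network
#'
#' Out-expected-influence of node `i` is the signed sum of its outgoing
#' cross-lagged weights `sum_{j != i} W[j, i]` (how strongly the symptom
#' predicts other symptoms at the next wave); in-expected-influence of node
#' `j` is the signed sum of incoming weights `sum_{i != j} W[j, i]`.
#' Autoregressive (diagonal) paths are excluded. z columns standardize each
#' index across the nodes (n-1 denominator).
#'
#' @param net a [clpn_network] (or a bare square weight matrix).
#' @return data frame of class `centrality_table` with columns `node`,
#'   `out_ei`, `in_ei`, `out_ei_z`, `in_ei_z`; the network's wave pair is
#'   attached as attribute `network`.
#' @export
expected_influence <- function(net) {
  W <- if (inherits(net, "clpn_network")) net$W else as.matrix(net)
  stopifnot(nrow(W) == ncol(W), all(is.finite(W)))
  nodes <- rownames(W) %||% paste0("V", seq_len(nrow(W)))
  diag(W) <- 0
  zstd <- function(x) if (sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / sd(x)
  out <- data.frame(
    node = nodes,
    out_ei = colSums(W),
    in_ei = rowSums(W),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$out_ei_z <- zstd(out$out_ei)
  out$in_ei_z <- zstd(out$in_ei)
  attr(out, "network") <- if (inherits(net, "clpn_network"))
    paste(net$wave_pair, collapse = "->") else NA_character_
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Correlation of centrality between two networks
#'
#' Pearson correlation of the per-node expected-influence values of two
#' networks over the same node set. Raw and z-standardized values give the
#' identical correlation (z-scoring is an affine map per network), so the
#' `scale` flag only affects which columns are read.
#'
#' @param a,b `centrality_table`s with identical `node` columns.
#' @param index `"out"` or `"in"`.
#' @param scale `"raw"` (default) or `"z"`.
#' @return Pearson r, or `NA` with a warning if either vector is constant.
#' @export
centrality_correlation <- function(a, b, index = c("out", "in"),
                                   scale = c("raw", "z")) {
  index <- match.arg(index)
  scale <- match.arg(scale)
  if (!identical(a$node, b$node)) stop("node sets differ")
  col <- paste0(index, "_ei", if (scale == "z") "_z" else "")
  x <- a[[col]]; y <- b[[col]]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant centrality vector; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}
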