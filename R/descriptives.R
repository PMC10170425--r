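#' Cronbach's alpha
#'
#' `alpha = (k/(k-1)) * (1 - sum(item variances) / var(sum score))` over the
#' supplied item matrix (sample variances, n-1 denominator). Rows with any
#' missing value are dropped.
#'
#' @param x numeric matrix, subjects x items.
#' @return alpha in (-Inf, 1], or `NA` with a warning when the sum score has
#'   zero variance.
#' @export
cronbach_alpha <- function(x) {
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  v_sum <- var(rowSums(x))
  if (!is.finite(v_sum) || v_sum <= 0) {
    warning("sum score has zero variance; alpha undefined")
    return(NA_real_)
  }
  (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / v_sum)
}

#' McDonald's omega total from a one-factor fit
#'
#' Fits a single common factor to the item covariance matrix by iterated
#' principal axis factoring (communalities initialized from squared multiple
#' correlations, refined until the largest change is below `tol`), then
#' reports `omega = (sum lambda)^2 / ((sum lambda)^2 + sum psi)` with
#' loadings sign-fixed so their sum is non-negative.
#'
#' @param x numeric matrix, subjects x items (complete cases used).
#' @param max_iter,tol iteration controls of the principal-axis loop.
#' @return omega in `[0, 1]`, or `NA` with a warning on non-convergence.
#' @export
omega_total <- function(x, max_iter = 500, tol = 1e-6) {
  x <- x[stats::complete.cases(x), , drop = FALSE]
  S <- stats::cov(x)
  p <- ncol(S)
  d <- diag(S)
  # start communalities: squared multiple correlations, with a fallback for
  # singular covariance matrices
  h2 <- tryCatch({
    Sinv <- solve(S)
    d - 1 / diag(Sinv)
  }, error = function(e) 0.5 * d)
  h2 <- pmin(pmax(h2, 1e-6), d * 0.999)
  converged <- FALSE
  lambda <- rep(0, p)
  for (iter in seq_len(max_iter)) {
    Sr <- S
    diag(Sr) <- h2
    e <- eigen(Sr, symmetric = TRUE)
    lambda <- sqrt(max(e$values[1], 0)) * e$vectors[, 1]
    if (sum(lambda) < 0) lambda <- -lambda
    h2_new <- pmin(lambda^2, d * 0.999)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      converged <- TRUE
      break
    }
    h2 <- h2_new
  }
  if (!converged) {
    warning("one-factor principal-axis fit did not converge; omega is NA")
    return(NA_real_)
  }
  psi <- pmax(d - lambda^2, 0)
  sl <- sum(lambda)
  sl^2 / (sl^2 + sum(psi))
}

#' Bias-adjusted sample skewness
#'
#' `G1 = g1 * sqrt(n (n-1)) / (n-2)` with `g1 = m3 / m2^(3/2)`.
#' @param x numeric vector (missing values dropped).
#' @return skewness, `NA` when `n < 3` or variance is 0.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Bias-adjusted excess kurtosis
#'
#' `G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3))` with `g2 = m4/m2^2 - 3`
#' (normal distribution = 0).
#' @param x numeric vector (missing values dropped).
#' @return excess kurtosis, `NA` when `n < 4` or variance is 0.
#' @export
sample_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  g2 <- mean((x - m)^4) / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Hedges's g for the change in GHQ sum scores
#'
#' Small-sample-corrected standardized mean difference
#' `g = J * (mean_b - mean_a) / s_pooled`, where `s_pooled` pools the two
#' waves' sum-score standard deviations and `J = 1 - 3/(4 df - 1)` with
#' `df = n - 1` pairs.
#'
#' @param a,b paired numeric vectors (earlier and later wave sum scores).
#' @return Hedges's g (positive when the later wave mean is higher).
#' @export
hedges_g <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) return(NA_real_)
  s_pooled <- sqrt((var(a) + var(b)) / 2)
  if (s_pooled == 0) return(0)
  df <- n - 1
  j <- 1 - 3 / (4 * df - 1)
  j * (mean(b) - mean(a)) / s_pooled
}

#' Descriptive statistics for a symptom panel
#'
#' Per item and wave: mean, sample SD, bias-adjusted skewness and excess
#' kurtosis. Per wave: number of scored subjects, GHQ sum-score mean and SD,
#' Cronbach's alpha and omega total over the 12 GHQ items, and the caseness
#' proportion (sum > 11). Per requested wave pair: paired t-test on the GHQ
#' sum scores of subjects scored at both waves (reported as earlier minus
#' later, so deterioration gives a negative t), `df = n_pairs - 1`, and
#' Hedges's g for the later-minus-earlier standardized change.
#'
#' @param data a [panel_dataset].
#' @param wave_pairs list of length-2 character vectors of wave labels;
#'   defaults to consecutive waves.
#' @return list of class `clpn_descriptives` with data frames `items`,
#'   `waves`, `pairs`.
#' @export
descriptives <- function(data, wave_pairs = NULL) {
  waves <- data$waves
  if (is.null(wave_pairs) && length(waves) >= 2)
    wave_pairs <- lapply(seq_len(length(waves) - 1),
                         function(i) waves[c(i, i + 1)])
  items <- do.call(rbind, lapply(waves, function(w) {
    m <- wave_matrix(data, w)
    data.frame(
      item = data$schema$item_id,
      wave = w,
      mean = colMeans(m, na.rm = TRUE),
      sd = apply(m, 2, sd, na.rm = TRUE),
      skewness = apply(m, 2, sample_skewness),
      kurtosis = apply(m, 2, sample_kurtosis),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  scores <- lapply(waves, function(w) ghq_sum_and_caseness(data, w))
  names(scores) <- waves
  wave_rows <- do.call(rbind, lapply(waves, function(w) {
    m <- wave_matrix(data, w)[, ghq_items(data$schema), drop = FALSE]
    s <- scores[[w]]$ghq_sum
    data.frame(
      wave = w,
      n = sum(!is.na(s)),
      ghq_sum_mean = mean(s, na.rm = TRUE),
      ghq_sum_sd = sd(s, na.rm = TRUE),
      alpha = cronbach_alpha(m),
      omega = omega_total(m),
      caseness = mean(scores[[w]]$case, na.rm = TRUE),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  pair_rows <- NULL
  if (length(wave_pairs) > 0) {
    pair_rows <- do.call(rbind, lapply(wave_pairs, function(wp) {
      a <- scores[[wp[1]]]$ghq_sum
      b <- scores[[wp[2]]]$ghq_sum
      ok <- !is.na(a) & !is.na(b)
      n <- sum(ok)
      if (n >= 2 && sd(a[ok] - b[ok]) > 0) {
        tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
        tval <- unname(tt$statistic); pval <- tt$p.value
      } else {
        tval <- 0; pval <- 1
      }
      data.frame(
        wave_a = wp[1], wave_b = wp[2], n_pairs = n, df = n - 1,
        t = tval, p = pval, hedges_g = hedges_g(a[ok], b[ok]),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }))
  }
  structure(list(items = items, waves = wave_rows, pairs = pair_rows),
            class = "clpn_descriptives")
}

#' @export
print.clpn_descriptives <- function(x, ...) {
  cat("Per-wave summary:\n")
  print(x$waves, digits = 4)
  if (!is.null(x$pairs)) {
    cat("\nWave-pair change tests:\n")
    print(x$pairs, digits = 4)
  }
  invisible(x)
}

#' Write a descriptives table to CSV
#'
#' One row per (item, wave), followed by a per-wave summary block and the
#' wave-pair tests; all floats rounded to 6 significant digits.
#'
#' @param x a `clpn_descriptives` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptives <- function(x, path) {
  sig <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    df
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(sig(x$items), con, row.names = FALSE, quote = FALSE)
  writeLines("", con)
  write.csv(sig(x$waves), con, row.names = FALSE, quote = FALSE)
  if (!is.null(x$pairs)) {
    writeLines("", con)
    write.csv(sig(x$pairs), con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
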