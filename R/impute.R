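#' Configuration for predictive mean matching imputation
#'
#' @param n_donors number of nearest-prediction donors to sample from
#'   (default 5).
#' @param max_iter number of chained-equation sweeps (default 10).
#' @param seed integer seed; determines the imputed dataset.
#' @param auxiliary auxiliary covariates entering every imputation model
#'   (default sex, ethnicity and age; the study convention of sex and
#'   ethnicity only is available by setting
#'   `auxiliary = c("sex", "ethnicity")`).
#' @return list of class `imputation_config`.
#' @export
imputation_config <- function(n_donors = 5, max_iter = 10, seed = 1,
                              auxiliary = c("sex", "ethnicity", "age")) {
  stopifnot(n_donors >= 1, max_iter >= 1)
  structure(list(n_donors = as.integer(n_donors),
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed),
                 auxiliary = auxiliary),
            class = "imputation_config")
}

#' Predictive mean matching imputation (single dataset)
#'
#' Chained equations over all incomplete item variables (every item at every
#' wave is one variable; predictors are all other item variables plus the
#' auxiliary covariates). For each incomplete variable per sweep: regress the
#' observed values on the predictors by least squares, draw perturbed
#' coefficients `beta* ~ N(beta_hat, sigma^2 (X'X)^-1)` (type-1 matching:
#' observed cases are predicted with `beta_hat`, missing cases with
#' `beta*`), find the `n_donors` observed cases with closest predictions,
#' and impute by drawing one donor's observed value uniformly at random.
#' Imputed values are therefore always values observed somewhere for that
#' variable, hence in scale range and ordinal. Variables are visited in
#' ascending order of missingness; missing cells are initialized by random
#' draws from the variable's observed values. Multiple imputation with
#' pooling is deliberately not offered: pooled networks are not
#' well-defined, so a single imputed dataset is the supported workflow.
#'
#' @param data a [panel_dataset].
#' @param config an [imputation_config].
#' @return a complete [panel_dataset].
#' @export
pmm_impute <- function(data, config = imputation_config()) {
  if (!anyNA(data$responses)) return(data)
  set.seed(config$seed)
  n <- length(data$subjects)
  p <- nrow(data$schema)
  w <- length(data$waves)
  # flatten to n x (p*w) with item_wave column names
  vars <- as.vector(outer(data$schema$item_id, data$waves, paste, sep = "_w"))
  M <- matrix(data$responses, n, p * w, dimnames = list(NULL, vars))
  miss <- is.na(M)
  n_miss <- colSums(miss)
  short <- which(n - n_miss < config$n_donors)
  if (length(short) > 0)
    stop(sprintf("variable '%s' has fewer than n_donors observed values",
                 vars[short[1]]))
  aux <- NULL
  if (!is.null(data$aux) && length(config$auxiliary) > 0) {
    aux_cols <- intersect(config$auxiliary, names(data$aux))
    aux <- as.matrix(data$aux[, aux_cols, drop = FALSE])
    for (j in seq_len(ncol(aux))) {       # mode/median fill, aux must be complete
      if (anyNA(aux[, j])) {
        obs <- aux[!is.na(aux[, j]), j]
        aux[is.na(aux[, j]), j] <- as.numeric(names(sort(table(obs),
                                                         decreasing = TRUE))[1])
      }
    }
  }
  # initialize missing cells from the observed marginal of each variable
  for (v in which(n_miss > 0))
    M[miss[, v], v] <- sample(M[!miss[, v], v], n_miss[v], replace = TRUE)
  visit <- order(n_miss)
  visit <- visit[n_miss[visit] > 0]
  for (sweep in seq_len(config$max_iter)) {
    for (v in visit) {
      obs <- !miss[, v]
      X <- cbind(1, M[, -v, drop = FALSE], aux)
      y <- M[obs, v]
      fit <- lm.fit(X[obs, , drop = FALSE], y)
      keep <- !is.na(fit$coefficients)
      beta <- fit$coefficients[keep]
      Xk <- X[, keep, drop = FALSE]
      rss <- sum(fit$residuals^2)
      dfres <- max(sum(obs) - length(beta), 1)
      sigma2 <- rss / dfres
      R <- qr.R(fit$qr)[seq_along(beta), seq_along(beta), drop = FALSE]
      zdraw <- rnorm(length(beta))
      beta_star <- beta + sqrt(sigma2) *
        tryCatch(backsolve(R, zdraw), error = function(e) rep(0, length(beta)))
      pred_obs <- drop(Xk[obs, , drop = FALSE] %*% beta)
      pred_mis <- drop(Xk[!obs, , drop = FALSE] %*% beta_star)
      if (any(!is.finite(pred_obs)) || any(!is.finite(pred_mis)))
        stop(sprintf("non-finite predictions while imputing '%s'", vars[v]))
      y_obs <- M[obs, v]
      imputed <- vapply(pred_mis, function(pm) {
        d <- abs(pred_obs - pm)
        donors <- order(d)[seq_len(config$n_donors)]
        y_obs[donors[sample.int(length(donors), 1)]]
      }, numeric(1))
      M[miss[, v], v] <- imputed
    }
  }
  data$responses <- array(M, c(n, p, w),
                          dimnames = dimnames(data$responses))
  validate_panel(data)
  data
}

#' Restrict to complete cases
#'
#' Keeps exactly the subjects with zero missing responses across the listed
#' waves (all items), for the complete-case sensitivity analysis.
#'
#' @param data a [panel_dataset].
#' @param waves wave labels to require (default: all waves).
#' @return a [panel_dataset] with the retained subjects.
#' @export
complete_cases <- function(data, waves = data$waves) {
  waves <- as.character(waves)
  sub <- data$responses[, , waves, drop = FALSE]
  keep <- apply(!is.na(sub), 1, all)
  message(sprintf("complete cases: %d of %d subjects retained",
                  sum(keep), length(keep)))
  if (!any(keep)) {
    warning("no complete cases remain")
  }
  data$responses <- data$responses[keep, , , drop = FALSE]
  data$subjects <- data$subjects[keep]
  if (!is.null(data$aux))
    data$aux <- data$aux[keep, , drop = FALSE]
  if (!is.null(data$latent))
    data$latent <- data$latent[keep, , , drop = FALSE]
  data
}
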