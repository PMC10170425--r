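#' Generating model for synthetic symptom panels
#'
#' Describes a sparse latent VAR(1) process over the item battery: the latent
#' value of item `j` at wave `t+1` is `B[j, ] %*% z_t + innovation`, where
#' `z_t` is the standardized wave-`t` latent vector. Latents are discretized
#' to each item's Likert range by ordered thresholds, and wave-level dropout
#' follows a logistic model on the auxiliary covariates.
#'
#' @param B signed weight matrix; `B[j, i]` is the effect of item `i` at wave
#'   `t` on item `j` at wave `t+1` (diagonal = autoregressive paths). Its
#'   spectral radius must be below 1.
#' @param innovation_sd per-item innovation standard deviation (>= 0).
#' @param wave1_cov positive semi-definite covariance of the first-wave
#'   latents.
#' @param thresholds list of per-item strictly increasing cut-point vectors;
#'   item `i` with `c` categories needs `c - 1` cut-points.
#' @param missingness_params named numeric vector
#'   `c(intercept, sex, ethnicity, age)` of logistic dropout coefficients
#'   (age enters standardized as `(age - 50)/20`).
#' @param schema an [item_schema] (defines category counts and labels).
#'
#' @return object of class `true_model`.
#' @export
true_model <- function(B, innovation_sd, wave1_cov, thresholds,
                       missingness_params =
                         c(intercept = -1.35, sex = 0.25,
                           ethnicity = 0.35, age = 0.30),
                       schema = default_item_schema()) {
  p <- nrow(schema)
  B <- as.matrix(B)
  stopifnot(nrow(B) == p, ncol(B) == p,
            length(innovation_sd) %in% c(1L, p),
            length(thresholds) == p)
  innovation_sd <- rep_len(innovation_sd, p)
  if (any(innovation_sd < 0)) stop("innovation_sd must be non-negative")
  rho <- max(abs(eigen(B, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("spectral radius of B is %.3f; must be < 1", rho))
  ev <- eigen(as.matrix(wave1_cov), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("wave1_cov is not positive semi-definite")
  n_cats <- schema$scale_max - schema$scale_min + 1
  for (i in seq_len(p)) {
    cuts <- thresholds[[i]]
    if (length(cuts) != n_cats[i] - 1)
      stop(sprintf("item '%s' needs %d cut-points, got %d",
                   schema$item_id[i], n_cats[i] - 1, length(cuts)))
    if (is.unsorted(cuts, strictly = TRUE))
      stop(sprintf("thresholds of item '%s' must be strictly increasing",
                   schema$item_id[i]))
  }
  structure(
    list(B = B, innovation_sd = innovation_sd,
         wave1_cov = as.matrix(wave1_cov), thresholds = thresholds,
         missingness_params = missingness_params, schema = schema,
         mask = B != 0),
    class = "true_model"
  )
}

#' Default 13-item generating model
#'
#' A fixture model echoing the qualitative structure reported for distress
#' networks: autoregressive diagonal 0.3; about 20 cross-lagged paths with
#' magnitudes 0.10-0.25; a designated out-hub (`loneliness`, largest true
#' out-expected-influence) and in-hub (`depressed`, many incoming paths);
#' a handful of additional seeded random paths, two of them negative.
#' Innovation SDs are set to `sqrt(1 - rowSums(B^2))` (floored at 0.1) so
#' latents stay near unit variance; first-wave latents are exchangeable with
#' correlation 0.3; thresholds are standard-normal quantiles chosen so that
#' category frequencies are right-skewed like observed symptom data.
#'
#' @param seed integer seed controlling the random extra paths.
#' @return a [true_model].
#' @export
default_true_model <- function(seed = 2023) {
  schema <- default_item_schema()
  items <- schema$item_id
  p <- length(items)
  B <- matrix(0, p, p, dimnames = list(items, items))
  diag(B) <- 0.3
  edge <- function(from, to, w) B[to, from] <<- w
  # hub structure: loneliness -> many, worthless -> confidence strongest,
  # depressed collects incoming paths
  edge("worthless", "confidence", 0.22)
  edge("loneliness", "depressed", 0.18)
  edge("loneliness", "confidence", 0.15)
  edge("loneliness", "worthless", 0.14)
  edge("loneliness", "difficulties", 0.12)
  edge("loneliness", "sleep", 0.10)
  edge("worthless", "difficulties", 0.13)
  edge("worthless", "depressed", 0.12)
  edge("confidence", "worthless", 0.10)
  edge("difficulties", "stress", 0.12)
  edge("stress", "depressed", 0.15)
  edge("difficulties", "depressed", 0.12)
  # seeded extra paths among the remaining items, small and mixed-sign
  set.seed(seed %% .Machine$integer.max)
  pool_from <- setdiff(items, "loneliness")
  n_extra <- 8
  added <- 0
  guard <- 0
  while (added < n_extra && guard < 1000) {
    guard <- guard + 1
    from <- sample(pool_from, 1)
    to <- sample(setdiff(items, from), 1)
    if (B[to, from] != 0) next
    if (sum(abs(B[setdiff(items, from), from])) > 0.35) next  # keep hub on top
    w <- runif(1, 0.10, 0.18) * if (added < 2) -1 else 1
    B[to, from] <- w
    added <- added + 1
  }
  innovation_sd <- sqrt(pmax(1 - rowSums(B^2), 0.1))
  wave1_cov <- matrix(0.3, p, p); diag(wave1_cov) <- 1
  positive <- c("concentrate", "useful", "decisions", "activities",
                "face_problems", "happy")
  negative <- c("sleep", "stress", "difficulties", "depressed", "confidence")
  thresholds <- lapply(items, function(it) {
    if (it == "loneliness") qnorm(c(0.65, 0.90))
    else if (it == "worthless") qnorm(c(0.70, 0.90, 0.97))
    else if (it %in% negative) qnorm(c(0.40, 0.80, 0.95))
    else qnorm(c(0.15, 0.85, 0.97))
  })
  names(thresholds) <- items
  true_model(B, innovation_sd, wave1_cov, thresholds, schema = schema)
}

#' True expected influence of a generating model
#'
#' Signed off-diagonal column/row sums of the true cross-lagged matrix, the
#' population counterpart of [expected_influence()].
#' @param model a [true_model].
#' @return data frame with `node`, `out_ei`, `in_ei`.
#' @export
true_expected_influence <- function(model) {
  B <- model$B
  diag(B) <- 0
  data.frame(node = model$schema$item_id,
             out_ei = colSums(B), in_ei = rowSums(B),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulation run configuration
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_waves number of waves (>= 2).
#' @param seed integer seed; fully determines the generated dataset.
#' @param missingness_on apply the model's covariate-dependent dropout?
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects, n_waves = 2, seed = 1,
                              missingness_on = FALSE) {
  stopifnot(n_subjects >= 1, n_waves >= 2)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_waves = as.integer(n_waves),
                 seed = as.integer(seed),
                 missingness_on = isTRUE(missingness_on)),
            class = "simulation_config")
}

#' Simulate an ordinal symptom panel from a latent VAR(1) process
#'
#' First-wave latents are drawn from `model$wave1_cov`; each later wave is
#' `B %*% z_t` plus Gaussian innovation, where `z_t` standardizes the
#' wave-`t` latents across subjects (so `B` lives on the same standardized
#' scale as the network estimator's coefficients). Latents are discretized
#' by the per-item thresholds into the item's Likert categories. Auxiliary
#' covariates (sex, ethnicity, age) are generated per subject; when
#' `config$missingness_on` the model's logistic dropout is applied via
#' [apply_mar_missingness()]. The latent values are attached as
#' `$latent` for recovery testing.
#'
#' @param model a [true_model].
#' @param config a [simulation_config].
#' @return a [panel_dataset] (with `$latent`).
#' @export
simulate_panel <- function(model, config) {
  set.seed(config$seed)
  n <- config$n_subjects
  w <- config$n_waves
  schema <- model$schema
  p <- nrow(schema)
  subjects <- sprintf("S%05d", seq_len(n))
  aux <- data.frame(
    subject = subjects,
    sex = rbinom(n, 1, 0.45),
    ethnicity = rbinom(n, 1, 0.18),
    age = pmin(pmax(round(rnorm(n, 50, 19)), 16), 95),
    stringsAsFactors = FALSE
  )
  latent <- array(NA_real_, c(n, p, w),
                  dimnames = list(subjects, schema$item_id, NULL))
  latent[, , 1] <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = model$wave1_cov)
  for (t in seq_len(w - 1)) {
    z <- scale_cols(latent[, , t, drop = TRUE])
    eps <- matrix(rnorm(n * p), n, p) *
      rep(model$innovation_sd, each = n)
    latent[, , t + 1] <- z %*% t(model$B) + eps
  }
  resp <- array(NA_real_, c(n, p, w))
  for (i in seq_len(p)) {
    cuts <- model$thresholds[[i]]
    resp[, i, ] <- schema$scale_min[i] +
      findInterval(latent[, i, ], cuts)
  }
  out <- panel_dataset(resp, subjects, as.character(seq_len(w)), schema,
                       aux = aux, latent = latent)
  if (config$missingness_on)
    out <- apply_mar_missingness(out, model, seed = config$seed + 1L)
  out
}

#' Apply covariate-dependent MAR missingness
#'
#' For every wave after the first, a subject's whole interview (all items) is
#' set missing with probability
#' `plogis(intercept + b_sex*sex + b_eth*ethnicity + b_age*(age-50)/20)`,
#' independently across waves; the first wave is always observed. With
#' `level = "item"` the same probability is applied independently per cell
#' instead (item nonresponse, useful for imputation tests). The marginal
#' missingness rate is reported via `message()`.
#'
#' @param data a [panel_dataset] with auxiliary covariates.
#' @param model a [true_model] (supplies `missingness_params`), or a named
#'   numeric vector of the four coefficients.
#' @param seed integer seed.
#' @param level `"wave"` (dropout, default) or `"item"`.
#' @return the [panel_dataset] with responses masked.
#' @export
apply_mar_missingness <- function(data, model, seed, level = "wave") {
  if (is.null(data$aux)) stop("auxiliary covariates required for MAR dropout")
  params <- if (inherits(model, "true_model")) model$missingness_params else model
  set.seed(as.integer(seed))
  eta <- params[["intercept"]] +
    params[["sex"]] * data$aux$sex +
    params[["ethnicity"]] * data$aux$ethnicity +
    params[["age"]] * (data$aux$age - 50) / 20
  pr <- plogis(eta)
  n <- length(data$subjects)
  w <- length(data$waves)
  p <- nrow(data$schema)
  for (t in 2:w) {
    if (level == "wave") {
      drop <- runif(n) < pr
      data$responses[drop, , t] <- NA_real_
    } else if (level == "item") {
      drop <- matrix(runif(n * p) < pr, n, p)
      data$responses[, , t][drop] <- NA_real_
    } else stop(sprintf("unknown level '%s'", level))
  }
  rate <- mean(is.na(data$responses[, , -1, drop = FALSE]))
  message(sprintf("MAR missingness applied: %.1f%% of post-baseline cells missing",
                  100 * rate))
  data
}

# Vectorized column standard deviations (n-1 denominator).
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  sqrt(pmax(colSums(m * m) - n * mu^2, 0) / (n - 1))
}

# Column-wise z-standardization with a zero-variance guard: constant columns
# are centered only (they carry no cross-sectional signal to propagate).
scale_cols <- function(m) {
  mu <- colMeans(m)
  s <- col_sds(m)
  s[!is.finite(s) | s < 1e-12] <- 1
  m <- m - rep(mu, each = nrow(m))
  m / rep(s, each = nrow(m))
}
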