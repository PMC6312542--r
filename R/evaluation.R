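# Heritability, genetic-correlation summaries, adjusted phenotypes and the
# accuracy metrics used in cross-validation.

#' Narrow-sense genomic heritability
#'
#' Per environment: `h2 = vG / (vG + vR)`.
#'
#' @param vG Additive genomic variance(s).
#' @param vR Residual variance(s).
#' @return Heritability value(s) in `[0, 1]`.
#' @export
heritability <- function(vG, vR) {
  if (any(vG < 0) || any(vR < 0)) stop("variances must be non-negative")
  if (any(vG + vR == 0)) stop("undefined heritability: vG + vR = 0")
  vG / (vG + vR)
}

#' Per-environment variance and heritability table from a fit
#'
#' @param fit A `gxe_fit`.
#' @return Data.frame with `env`, `vG` (implied additive variance, the
#'   diagonal of the environment covariance), `vR`, `vP = vG + vR`, `h2`.
#' @export
heritability_table <- function(fit) {
  stopifnot(inherits(fit, "gxe_fit"))
  Sig <- env_cov_matrix(fit$structure, length(fit$envs))
  vG <- diag(Sig)
  vR <- as.numeric(fit$resid_vars)
  data.frame(
    env = fit$envs, vG = vG, vR = vR, vP = vG + vR,
    h2 = heritability(vG, vR),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Average cross-environment additive genetic correlation
#'
#' From the compound-symmetry decomposition: the common covariance over the
#' common total variance, `r = sigma2_A / (sigma2_A + sigma2_AxE)`.
#'
#' @param sigma2_A Additive (main-effect) variance — the common
#'   off-diagonal of the CS structure.
#' @param sigma2_AxE Interaction variance — diagonal minus off-diagonal.
#' @return The average genetic correlation among environments.
#' @export
avg_env_correlation <- function(sigma2_A, sigma2_AxE) {
  if (sigma2_A < 0 || sigma2_AxE < 0) stop("variances must be non-negative")
  if (sigma2_A + sigma2_AxE == 0) stop("undefined correlation: both variances zero")
  sigma2_A / (sigma2_A + sigma2_AxE)
}

#' Prediction accuracy from predictive ability
#'
#' `PACC = PA / sqrt(h2)`; may exceed 1 when the validation set is closely
#' related to the training set.
#'
#' @param PA Predictive ability (correlation of predictions with adjusted
#'   phenotypes).
#' @param h2 Narrow-sense heritability of the target environment.
#' @return Prediction accuracy.
#' @export
prediction_accuracy <- function(PA, h2) {
  if (any(h2 <= 0) || any(h2 > 1)) stop("h2 must be in (0, 1]")
  PA / sqrt(h2)
}

#' Standard error of prediction accuracy
#'
#' `se = 1 / sqrt(n)` with `n` the validation-population size.
#'
#' @param n Number of individuals in the validation population.
#' @return Standard error(s).
#' @export
se_pacc <- function(n) {
  if (any(n < 1)) stop("validation population must have at least 1 individual")
  1 / sqrt(n)
}

#' Adjusted phenotypes (fixed effects removed)
#'
#' Subtracts each record's fitted fixed effects (environment mean and,
#' where applicable, planting-year effect) estimated from a full-data fit.
#' No shrinkage is applied: only the BLUE part is removed.
#'
#' @param data A [model_data()].
#' @param fit A converged `gxe_fit` on the same data.
#' @param G_A Relationship matrix (used to rebuild the design).
#' @return Data.frame with `id`, `env`, `location`, `season`, `y_adj`, one
#'   row per observation.
#' @export
adjust_phenotypes <- function(data, fit, G_A) {
  stopifnot(inherits(data, "model_data"), inherits(fit, "gxe_fit"))
  design <- build_design(data, ids = rownames(G_A))
  bad <- setdiff(colnames(design$X), names(fit$blue))
  if (length(bad)) {
    stop("record factor level(s) absent from fit: ",
         paste(bad, collapse = ", "))
  }
  Xb <- as.numeric(design$X %*% fit$blue[colnames(design$X)])
  data.frame(
    id = data$id,
    env = as.character(data$env),
    location = as.character(data$location),
    season = data$season,
    y_adj = data$y - Xb,
    stringsAsFactors = FALSE
  )
}
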