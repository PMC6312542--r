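# Genotype-by-environment covariance structures for the multivariate
# genomic model. The full covariance of breeding values is
# G = G_AxE (x) G_A (environment-major Kronecker layout).

#' Parameterize a genotype-by-environment covariance structure
#'
#' Three nested parameterisations of the `n_E x n_E` additive
#' genetic-by-environment covariance matrix:
#' * `uniform` — one additive variance, perfect correlation across
#'   environments: `sigma2_A * J`.
#' * `cs` (compound symmetry, main effect + interaction) — common
#'   covariance `sigma2_A` off the diagonal, `sigma2_A + sigma2_AxE` on it.
#' * `fa1` (first-order factor-analytic) — `Lambda Lambda' + diag(Psi)`
#'   with one loading and one specific variance per environment; the sign
#'   convention is `Lambda[1] >= 0`.
#'
#' @param kind `"uniform"`, `"cs"` or `"fa1"`.
#' @param sigma2_A Additive variance (uniform, cs).
#' @param sigma2_AxE Interaction variance (cs).
#' @param Lambda Numeric vector of environment loadings (fa1).
#' @param Psi Numeric vector of environment-specific variances (fa1).
#' @param envs Optional environment labels.
#' @return An object of class `env_cov_structure`.
#' @export
env_cov_structure <- function(kind = c("uniform", "cs", "fa1"),
                              sigma2_A = NULL, sigma2_AxE = NULL,
                              Lambda = NULL, Psi = NULL, envs = NULL) {
  kind <- match.arg(kind)
  s <- switch(kind,
    uniform = {
      stopifnot(!is.null(sigma2_A))
      if (sigma2_A < 0) stop("sigma2_A must be non-negative")
      list(kind = kind, sigma2_A = sigma2_A)
    },
    cs = {
      stopifnot(!is.null(sigma2_A), !is.null(sigma2_AxE))
      if (sigma2_A < 0 || sigma2_AxE < 0) {
        stop("variance parameters must be non-negative")
      }
      list(kind = kind, sigma2_A = sigma2_A, sigma2_AxE = sigma2_AxE)
    },
    fa1 = {
      stopifnot(!is.null(Lambda), !is.null(Psi),
                length(Lambda) == length(Psi))
      if (any(Psi < 0)) stop("specific variances Psi must be non-negative")
      if (Lambda[1] < 0) Lambda <- -Lambda # sign convention
      list(kind = kind, Lambda = as.numeric(Lambda), Psi = as.numeric(Psi))
    }
  )
  s$envs <- envs
  structure(s, class = "env_cov_structure")
}

#' Environment covariance matrix implied by a structure
#'
#' @param s An [env_cov_structure()].
#' @param n_E Number of environments (required for `uniform`/`cs`; for
#'   `fa1` it defaults to `length(Lambda)`).
#' @return The `n_E x n_E` implied covariance matrix `G_AxE`.
#' @export
env_cov_matrix <- function(s, n_E = NULL) {
  stopifnot(inherits(s, "env_cov_structure"))
  if (s$kind == "fa1") {
    if (is.null(n_E)) n_E <- length(s$Lambda)
    stopifnot(n_E == length(s$Lambda))
  }
  stopifnot(!is.null(n_E))
  M <- switch(s$kind,
    uniform = matrix(s$sigma2_A, n_E, n_E),
    cs = matrix(s$sigma2_A, n_E, n_E) + diag(s$sigma2_AxE, n_E),
    fa1 = tcrossprod(s$Lambda) + diag(s$Psi, n_E)
  )
  if (!is.null(s$envs)) dimnames(M) <- list(s$envs, s$envs)
  M
}

#' Implied cross-environment genetic correlations
#'
#' @param s An [env_cov_structure()] (or an already-built covariance
#'   matrix).
#' @param n_E Number of environments when `s` is a structure.
#' @return Correlation matrix with unit diagonal.
#' @export
implied_env_correlations <- function(s, n_E = NULL) {
  M <- if (inherits(s, "env_cov_structure")) env_cov_matrix(s, n_E) else as.matrix(s)
  v <- diag(M)
  if (any(v <= 0)) stop("undefined correlation: zero diagonal variance")
  C <- M / sqrt(outer(v, v))
  diag(C) <- 1
  C
}

# ---- internal parameter-vector plumbing used by the REML fitter ----------

# number of G_AxE parameters for a structure kind
n_struct_par <- function(kind, n_E) {
  switch(kind, uniform = 1L, cs = 2L, fa1 = 2L * n_E)
}

# build an env_cov_structure from the leading elements of a parameter vector
par_to_struct <- function(kind, theta, n_E, envs = NULL) {
  switch(kind,
    uniform = env_cov_structure("uniform", sigma2_A = theta[1], envs = envs),
    cs = env_cov_structure("cs", sigma2_A = theta[1], sigma2_AxE = theta[2],
                           envs = envs),
    fa1 = env_cov_structure("fa1", Lambda = theta[seq_len(n_E)],
                            Psi = theta[n_E + seq_len(n_E)], envs = envs)
  )
}

# derivative of G_AxE with respect to structure parameter k (n_E x n_E)
d_env_cov <- function(kind, theta, n_E, k) {
  if (kind == "uniform") {
    return(matrix(1, n_E, n_E))
  }
  if (kind == "cs") {
    return(if (k == 1L) matrix(1, n_E, n_E) else diag(1, n_E))
  }
  # fa1: k in 1..n_E are loadings, n_E+1 .. 2 n_E are specific variances
  if (k <= n_E) {
    lam <- theta[seq_len(n_E)]
    D <- matrix(0, n_E, n_E)
    D[k, ] <- lam
    D[, k] <- D[, k] + lam
    D
  } else {
    e <- k - n_E
    D <- matrix(0, n_E, n_E)
    D[e, e] <- 1
    D
  }
}
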