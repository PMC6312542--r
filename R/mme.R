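# BLUE / BLUP prediction from Henderson's mixed model equations.
#
# The solution is computed through the equivalent variance-form identities
#   b_hat = (X' V^-1 X)^-1 X' V^-1 y,
#   u_hat = G Z' V^-1 (y - X b_hat),
# which are exactly the MME solution for the same (bent) G and R; the MME
# residual identity is verified in the test suite. Working in V-space keeps
# the uniform structure (singular G_AxE) usable, since no G inverse is
# required.

#' Solve for fixed-effect BLUEs and genomic BLUPs
#'
#' Predicts the breeding value of every individual in every environment —
#' including (individual, environment) cells with no records, which borrow
#' information through `G_A` and the cross-environment covariance.
#'
#' @param data A [model_data()].
#' @param G_A Genomic relationship matrix.
#' @param fit A `gxe_fit` (or a list with elements `structure`,
#'   `resid_vars`, optional `resid_cov`, `bend`).
#' @param pev Also compute per-cell prediction-error variances? (One dense
#'   `N x (n_G n_E)` product; skip for repeated cross-validation refits.)
#' @return A list of class `gxe_blup`: `blue` (named vector), `blue_cov`,
#'   `blup` (`n_G x n_E` matrix of breeding values), `pev` (matching matrix
#'   or `NULL`), `fitted_fixed` (per record), `envs`, `ids`.
#' @export
solve_mme <- function(data, G_A, fit, pev = TRUE) {
  stopifnot(!is.null(fit$structure), !is.null(fit$resid_vars))
  bend <- if (!is.null(fit$bend)) fit$bend else 1e-6
  ctx <- reml_context(data, G_A, fit$structure$kind,
                      resid_cov = !is.null(fit$resid_cov), bend = bend)
  theta_s <- switch(fit$structure$kind,
    uniform = fit$structure$sigma2_A,
    cs = c(fit$structure$sigma2_A, fit$structure$sigma2_AxE),
    fa1 = c(fit$structure$Lambda, fit$structure$Psi)
  )
  vR <- rep_len(as.numeric(fit$resid_vars), ctx$nE)
  cc <- if (length(ctx$cov_locs)) {
    as.numeric(fit$resid_cov[ctx$cov_locs])
  } else {
    numeric(0)
  }
  theta <- c(theta_s, vR, cc)
  V <- reml_build_V(ctx, theta)
  ch <- chol(V)
  X <- ctx$X
  y <- ctx$y
  ViX <- backsolve(ch, forwardsolve(t(ch), X))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, ViX)
  chx <- chol(XtViX)
  beta <- backsolve(chx, forwardsolve(t(chx), crossprod(X, Viy)))
  resid <- y - X %*% beta
  w <- backsolve(ch, forwardsolve(t(ch), resid)) # V^-1 (y - Xb)
  Sig <- env_cov_matrix(fit$structure, ctx$nE)
  Gb <- bend_matrix(unclass(G_A), bend)
  A <- Gb[, ctx$design$id_index, drop = FALSE] # n_G x N
  nG <- nrow(Gb)
  blup <- matrix(0, nG, ctx$nE,
                 dimnames = list(rownames(Gb), ctx$design$envs))
  for (f in seq_len(ctx$nE)) {
    blup[, f] <- A %*% (Sig[f, ctx$ei] * w)
  }
  pev_mat <- NULL
  if (pev) {
    # pev(f, i) = G[(f,i),(f,i)] - g' P g, g = cov(u_cell, y)
    Vinv <- chol2inv(ch)
    WX <- backsolve(chx, forwardsolve(t(chx), t(ViX)))
    P <- Vinv - ViX %*% WX
    pev_mat <- matrix(0, nG, ctx$nE,
                      dimnames = dimnames(blup))
    for (f in seq_len(ctx$nE)) {
      Gcell <- A * rep(Sig[f, ctx$ei], each = nG) # rows: g' for each ind
      quad <- rowSums((Gcell %*% P) * Gcell)
      pev_mat[, f] <- Sig[f, f] * diag(Gb) - quad
    }
  }
  blue_cov <- chol2inv(chx)
  dimnames(blue_cov) <- list(colnames(X), colnames(X))
  structure(
    list(
      blue = stats::setNames(as.numeric(beta), colnames(X)),
      blue_cov = blue_cov,
      blup = blup,
      pev = pev_mat,
      fitted_fixed = as.numeric(X %*% beta),
      envs = ctx$design$envs,
      ids = rownames(Gb)
    ),
    class = "gxe_blup"
  )
}

#' @export
print.gxe_blup <- function(x, ...) {
  cat("gxe_blup:", nrow(x$blup), "individuals x", ncol(x$blup),
      "environments\n")
  invisible(x)
}
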