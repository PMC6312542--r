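# Model comparison and environment-mean inference.

#' Likelihood-ratio test between nested REML fits
#'
#' Statistic `2 (logL_full - logL_nested)` referred to a chi-square with
#' `df` degrees of freedom. The naive chi-square reference is used even
#' when parameters sit on a variance boundary (the boundary-mixture
#' refinement is deliberately not applied). A negative statistic beyond
#' numerical tolerance indicates convergence trouble; it is reported with a
#' warning and `p = 1`.
#'
#' @param nested,full `gxe_fit` objects (or any list with `loglik`).
#' @param df Difference in number of parameters.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(nested, full, df) {
  stopifnot(df >= 1)
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-6) {
    warning("negative LRT statistic (", format(stat),
            "): convergence problem in the full model; p set to 1")
    return(list(statistic = stat, df = df, p_value = 1))
  }
  stat <- max(stat, 0)
  list(
    statistic = stat,
    df = df,
    p_value = stats::pchisq(stat, df = df, lower.tail = FALSE)
  )
}

#' Degrees of freedom separating two G x E structures
#'
#' @param nested,full Structure kinds (`"uniform"`, `"cs"`, `"fa1"`).
#' @param n_E Number of environments.
#' @return Integer df for [lrt()].
#' @export
structure_df <- function(nested, full, n_E) {
  np <- function(kind) n_struct_par(kind, n_E)
  d <- np(full) - np(nested)
  if (d <= 0) stop("structures are not nested in this order")
  d
}

#' Environment least-square means with compact letter display
#'
#' Re-expands the treatment-coded fixed effects to adjusted cell means per
#' environment (averaging over planting-year levels at the location where
#' that factor applies), tests all pairwise differences with z-tests from
#' the BLUE covariance, and assigns compact letters at level `alpha`:
#' environments sharing a letter are not significantly different. Letters
#' are derived from the maximal cliques of the non-significance graph, so
#' the display does not depend on the input ordering of environments.
#'
#' @param fit A `gxe_fit`.
#' @param alpha Significance level for the pairwise tests.
#' @return Data.frame with `env`, `lsmean`, `se`, `letters`, ordered by
#'   mean.
#' @export
lsmeans_envs <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "gxe_fit"))
  if (!fit$converged) warning("fit did not converge; means may be unstable")
  cn <- names(fit$blue)
  envs <- fit$envs
  nE <- length(envs)
  L <- matrix(0, nE, length(fit$blue), dimnames = list(envs, cn))
  L[, "(Intercept)"] <- 1
  for (e in seq_len(nE)[-1L]) {
    L[e, paste0("env", envs[e])] <- 1
  }
  py_cols <- grep("^py", cn, value = TRUE)
  if (length(py_cols) && !is.null(fit$py_location)) {
    n_lev <- length(py_cols) + 1L # reference level contributes zero
    at <- startsWith(envs, paste0(fit$py_location, ":"))
    L[at, py_cols] <- 1 / n_lev
  }
  mu <- as.numeric(L %*% fit$blue)
  cv <- L %*% fit$blue_cov %*% t(L)
  se <- sqrt(diag(cv))
  nonsig <- matrix(TRUE, nE, nE)
  for (a in seq_len(nE - 1L)) {
    for (b in seq(a + 1L, nE)) {
      sed <- sqrt(cv[a, a] + cv[b, b] - 2 * cv[a, b])
      z <- abs(mu[a] - mu[b]) / sed
      p <- 2 * stats::pnorm(-z)
      nonsig[a, b] <- nonsig[b, a] <- p >= alpha
    }
  }
  out <- data.frame(
    env = envs, lsmean = mu, se = se,
    letters = cld_letters(mu, nonsig),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$lsmean), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Compact letter display: each maximal clique of the non-significance graph
# gets one letter; cliques are ordered by the smallest mean they contain so
# "a" goes to the group with the lowest means.
cld_letters <- function(mu, nonsig) {
  n <- length(mu)
  cliques <- list()
  # Bron-Kerbosch (no pivoting; n is small)
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- sort(R)
      return(invisible())
    }
    for (v in P) {
      nb <- which(nonsig[v, ] & seq_len(n) != v)
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  ord <- order(vapply(cliques, function(cl) min(mu[cl]), numeric(1)))
  cliques <- cliques[ord]
  lab <- rep("", n)
  for (k in seq_along(cliques)) {
    lab[cliques[[k]]] <- paste0(lab[cliques[[k]]], letters[k])
  }
  lab
}
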