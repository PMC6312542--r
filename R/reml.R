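# Average-information REML for the multivariate genomic G x E model
#
#   y = Xb + Zu + r,   var(y) = Z (G_AxE (x) G_A) Z' + R
#
# Records are indexed by (individual, environment); the phenotypic
# covariance is assembled without forming Z explicitly:
#   V[r, s] = G_AxE[env(r), env(s)] * G_A[id(r), id(s)] + R[r, s].
# R is diagonal with one residual variance per environment, optionally with
# a per-location covariance between seasons for records of the same
# experimental unit.

# ---- parameter layout ----------------------------------------------------
# theta = c(structure parameters, residual variances (one per environment),
#           optional per-location season covariances)

# Context: everything fixed across iterations for a data set.
reml_context <- function(data, G_A, kind, resid_cov = FALSE,
                         bend = 1e-6) {
  design <- build_design(data, ids = rownames(G_A))
  N <- length(data$y)
  nE <- length(design$envs)
  Gb <- bend_matrix(unclass(G_A), bend)
  K <- Gb[design$id_index, design$id_index, drop = FALSE]
  ei <- design$env_index
  E <- matrix(0, N, nE)
  E[cbind(seq_len(N), ei)] <- 1
  # per-location same-unit cross-season record pairs (for residual covariance)
  cov_locs <- character(0)
  pair_list <- list()
  if (resid_cov) {
    loc <- as.character(data$location)
    for (l in levels(data$location)) {
      prs <- NULL
      for (u in unique(data$unit[loc == l])) {
        recs <- which(data$unit == u & loc == l)
        if (length(recs) >= 2L) {
          cmb <- utils::combn(recs, 2L)
          prs <- cbind(prs, cmb)
        }
      }
      if (!is.null(prs) && ncol(prs)) {
        cov_locs <- c(cov_locs, l)
        pair_list[[l]] <- prs
      }
    }
  }
  ns <- n_struct_par(kind, nE)
  list(
    data = data, design = design, N = N, nE = nE, kind = kind,
    K = K, ei = ei, E = E, y = data$y, X = design$X,
    ns = ns, n_par = ns + nE + length(cov_locs),
    cov_locs = cov_locs, pair_list = pair_list
  )
}

# V matrix for a parameter vector
reml_build_V <- function(ctx, theta) {
  s <- par_to_struct(ctx$kind, theta[seq_len(ctx$ns)], ctx$nE)
  Sig <- env_cov_matrix(s, ctx$nE)
  vR <- theta[ctx$ns + seq_len(ctx$nE)]
  V <- Sig[ctx$ei, ctx$ei, drop = FALSE] * ctx$K
  diag(V) <- diag(V) + vR[ctx$ei]
  if (length(ctx$cov_locs)) {
    cc <- theta[ctx$ns + ctx$nE + seq_along(ctx$cov_locs)]
    for (i in seq_along(ctx$cov_locs)) {
      prs <- ctx$pair_list[[ctx$cov_locs[i]]]
      V[cbind(prs[1, ], prs[2, ])] <- V[cbind(prs[1, ], prs[2, ])] + cc[i]
      V[cbind(prs[2, ], prs[1, ])] <- V[cbind(prs[2, ], prs[1, ])] + cc[i]
    }
  }
  V
}

# core REML evaluation; returns NULL if V or X'V^-1 X is not PD
reml_eval <- function(ctx, theta, need_P = FALSE) {
  V <- reml_build_V(ctx, theta)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  X <- ctx$X
  y <- ctx$y
  p <- ncol(X)
  logdetV <- 2 * sum(log(diag(ch)))
  ViX <- backsolve(ch, forwardsolve(t(ch), X))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  logdetX <- 2 * sum(log(diag(chx)))
  XtViy <- crossprod(X, Viy)
  beta <- backsolve(chx, forwardsolve(t(chx), XtViy))
  ytPy <- sum(y * Viy) - sum(XtViy * beta)
  ll <- -0.5 * ((ctx$N - p) * log(2 * pi) + logdetV + logdetX + ytPy)
  out <- list(loglik = as.numeric(ll), beta = as.numeric(beta),
              XtViX = XtViX, chx = chx)
  if (need_P) {
    Vinv <- chol2inv(ch)
    WX <- backsolve(chx, forwardsolve(t(chx), t(ViX))) # (X'ViX)^-1 X'Vi
    P <- Vinv - ViX %*% WX
    out$P <- (P + t(P)) / 2
    out$Py <- as.numeric(out$P %*% y)
  }
  out
}

# derivative apparatus: traces tr(P dV_k) and vectors w_k = dV_k %*% Py
reml_derivs <- function(ctx, theta, P, Py) {
  q <- ctx$n_par
  N <- ctx$N
  tr <- numeric(q)
  W <- matrix(0, N, q)
  Tmat <- crossprod(ctx$E, (P * ctx$K) %*% ctx$E) # nE x nE aggregation
  Q <- ctx$K %*% (ctx$E * Py)                     # N x nE
  for (k in seq_len(ctx$ns)) {
    D <- d_env_cov(ctx$kind, theta[seq_len(ctx$ns)], ctx$nE, k)
    tr[k] <- sum(D * Tmat)
    W[, k] <- rowSums(D[ctx$ei, , drop = FALSE] * Q)
  }
  dP <- diag(P)
  for (e in seq_len(ctx$nE)) {
    k <- ctx$ns + e
    sel <- ctx$ei == e
    tr[k] <- sum(dP[sel])
    W[sel, k] <- Py[sel]
  }
  if (length(ctx$cov_locs)) {
    for (i in seq_along(ctx$cov_locs)) {
      k <- ctx$ns + ctx$nE + i
      prs <- ctx$pair_list[[ctx$cov_locs[i]]]
      tr[k] <- 2 * sum(P[cbind(prs[1, ], prs[2, ])])
      w <- numeric(N)
      for (j in seq_len(ncol(prs))) {
        a <- prs[1, j]; b <- prs[2, j]
        w[a] <- w[a] + Py[b]
        w[b] <- w[b] + Py[a]
      }
      W[, k] <- w
    }
  }
  list(tr = tr, W = W)
}

#' Restricted log-likelihood of the G x E genomic model
#'
#' Evaluates
#' `l_R = -1/2 [ (N - p) log 2 pi + log|V| + log|X' V^-1 X| + y' P y ]`
#' with `V = Z (G_AxE (x) G_A) Z' + R` and
#' `P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1`. The value is invariant to
#' translating `y` by any vector in the column span of `X`.
#'
#' @param data A [model_data()].
#' @param G_A Genomic relationship matrix over the individuals in `data`.
#' @param structure An [env_cov_structure()].
#' @param resid_vars Residual variances, one per environment (recycled if
#'   scalar), in the order of `data$envs`.
#' @param resid_cov Optional named vector of per-location same-unit season
#'   covariances.
#' @param bend Diagonal offset applied to `G_A` before use.
#' @return The restricted log-likelihood (scalar). Errors if `V` or
#'   `X'V^-1X` is singular (consider bending or checking the design).
#' @export
reml_loglik <- function(data, G_A, structure, resid_vars, resid_cov = NULL,
                        bend = 1e-6) {
  ctx <- reml_context(data, G_A, structure$kind,
                      resid_cov = !is.null(resid_cov), bend = bend)
  theta_s <- switch(structure$kind,
    uniform = structure$sigma2_A,
    cs = c(structure$sigma2_A, structure$sigma2_AxE),
    fa1 = c(structure$Lambda, structure$Psi)
  )
  vR <- rep_len(resid_vars, ctx$nE)
  cc <- if (length(ctx$cov_locs)) {
    as.numeric(resid_cov[ctx$cov_locs])
  } else {
    numeric(0)
  }
  ev <- reml_eval(ctx, c(theta_s, vR, cc))
  if (is.null(ev)) {
    stop("V or X'V^-1X is singular; bend the relationship matrix or check ",
         "the design")
  }
  ev$loglik
}

# starting values from per-environment phenotypic variances
reml_start <- function(ctx) {
  v <- tapply(ctx$y, ctx$ei, stats::var)
  v <- as.numeric(v)[seq_len(ctx$nE)]
  v[is.na(v) | v <= 0] <- stats::var(ctx$y)
  vbar <- mean(v)
  th_s <- switch(ctx$kind,
    uniform = vbar / 2,
    cs = c(0.4 * vbar, 0.1 * vbar),
    fa1 = c(sqrt(v / 2), 0.1 * v)
  )
  c(th_s, v / 2, rep(0, length(ctx$cov_locs)))
}

# lower bounds; residual variances floored strictly above zero to keep V PD
reml_bounds <- function(ctx) {
  vfloor <- 1e-6 * stats::var(ctx$y)
  lb_s <- switch(ctx$kind,
    uniform = 0,
    cs = c(0, 0),
    fa1 = c(rep(-Inf, ctx$nE), rep(0, ctx$nE))
  )
  c(lb_s, rep(vfloor, ctx$nE), rep(-Inf, length(ctx$cov_locs)))
}

project_theta <- function(ctx, theta, lb) {
  theta <- pmax(theta, lb)
  if (ctx$kind == "fa1" && theta[1] < 0) {
    theta[seq_len(ctx$nE)] <- -theta[seq_len(ctx$nE)]
  }
  theta
}

#' Fit the G x E genomic mixed model by AI-REML
#'
#' Maximizes the restricted log-likelihood over the parameters of the
#' chosen genotype-by-environment covariance structure plus per-environment
#' residual variances (and optional per-location season covariances of the
#' residuals). Updates use the average-information algorithm with
#' Levenberg-style damping and step-halving; when no damped AI step
#' improves the likelihood, an EM-type multiplicative update of the
#' variance parameters is tried before declaring convergence. Variance
#' parameters are constrained non-negative (pinned at the boundary when the
#' score pushes outward) and the factor-analytic sign is fixed by
#' `Lambda[1] >= 0`.
#'
#' @param data A [model_data()].
#' @param G_A Genomic relationship matrix (bent internally).
#' @param kind `"uniform"`, `"cs"` or `"fa1"`.
#' @param resid_cov Estimate a per-location same-unit season covariance?
#' @param start Optional full starting parameter vector.
#' @param tol_logL Convergence tolerance on the log-likelihood change.
#' @param tol_par Convergence tolerance on the maximum relative parameter
#'   change.
#' @param max_iter Maximum AI iterations.
#' @param max_halving Step halvings per iteration.
#' @param bend Diagonal offset for `G_A`.
#' @param verbose Print per-iteration progress?
#' @return An object of class `gxe_fit`: `structure`
#'   ([env_cov_structure()] at the optimum), `resid_vars` (named),
#'   `resid_cov` (named or NULL), `loglik`, `converged`, `trace`
#'   (data.frame), `blue` (fixed-effect estimates), `blue_cov`, `theta`,
#'   `envs`, `kind`, `n_records`, plus the inputs needed for prediction.
#' @export
fit_reml <- function(data, G_A, kind = c("fa1", "cs", "uniform"),
                     resid_cov = FALSE, start = NULL,
                     tol_logL = 1e-6, tol_par = 1e-4, max_iter = 200,
                     max_halving = 10, bend = 1e-6, verbose = FALSE) {
  kind <- match.arg(kind)
  if (kind != "uniform" && length(unique(as.character(data$env))) < 2L) {
    stop("cs/fa1 structures need at least 2 environments")
  }
  ctx <- reml_context(data, G_A, kind, resid_cov = resid_cov, bend = bend)
  lb <- reml_bounds(ctx)
  theta <- if (is.null(start)) reml_start(ctx) else as.numeric(start)
  stopifnot(length(theta) == ctx$n_par)
  theta <- project_theta(ctx, theta, lb)
  ev <- reml_eval(ctx, theta, need_P = TRUE)
  if (is.null(ev)) stop("starting values give a singular V; supply `start`")
  trace <- data.frame(iter = 0L, loglik = ev$loglik, step = NA_real_,
                      method = "start", stringsAsFactors = FALSE)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dv <- reml_derivs(ctx, theta, ev$P, ev$Py)
    score <- -0.5 * (dv$tr - as.numeric(crossprod(dv$W, ev$Py)))
    PW <- ev$P %*% dv$W
    AI <- 0.5 * crossprod(dv$W, PW)
    # freeze parameters pinned at a bound with an outward-pushing score
    at_bound <- is.finite(lb) & theta <= lb & score < 0
    free <- which(!at_bound)
    if (!length(free)) {
      converged <- TRUE
      break
    }
    accepted <- FALSE
    method <- "AI"
    ridge <- 0
    dAI <- mean(abs(diag(AI)[free])) + 1e-12
    for (attempt in 1:4) { # escalate damping if the step is bad
      delta <- numeric(ctx$n_par)
      sol <- tryCatch(
        solve(AI[free, free, drop = FALSE] +
                diag(ridge + 1e-10 * dAI, length(free)), score[free]),
        error = function(e) NULL
      )
      if (is.null(sol)) {
        ridge <- if (ridge == 0) 0.1 * dAI else ridge * 10
        next
      }
      delta[free] <- sol
      step <- 1
      for (h in seq_len(max_halving)) {
        cand <- project_theta(ctx, theta + step * delta, lb)
        evc <- reml_eval(ctx, cand, need_P = TRUE)
        if (!is.null(evc) && evc$loglik >= ev$loglik - 1e-10) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (accepted) break
      ridge <- if (ridge == 0) 0.1 * dAI else ridge * 10
    }
    if (!accepted) {
      # EM-type multiplicative fallback for the variance parameters
      method <- "EM"
      cand <- theta
      for (k in seq_len(ctx$n_par)) {
        is_lambda <- ctx$kind == "fa1" && k <= ctx$nE
        is_cov <- k > ctx$ns + ctx$nE
        if (is_lambda || is_cov) next
        u <- sum(dv$W[, k] * ev$Py)
        t_k <- dv$tr[k]
        if (t_k > 0 && u >= 0 && cand[k] > 0) {
          cand[k] <- cand[k] * sqrt(u / t_k)
        }
      }
      cand <- project_theta(ctx, cand, lb)
      step <- 1
      evc <- reml_eval(ctx, cand, need_P = TRUE)
      if (is.null(evc) || evc$loglik < ev$loglik - 1e-10) {
        converged <- TRUE # no direction improves beyond tolerance
        break
      }
    }
    dll <- evc$loglik - ev$loglik
    rel <- max(abs(cand - theta) / pmax(abs(theta), 1e-8))
    theta <- cand
    ev <- evc
    trace <- rbind(trace, data.frame(iter = it, loglik = ev$loglik,
                                     step = step, method = method,
                                     stringsAsFactors = FALSE))
    if (verbose) {
      cat(sprintf("iter %3d  logL %.6f  dlogL %.2e  (%s)\n",
                  it, ev$loglik, dll, method))
    }
    if (abs(dll) < tol_logL && rel < tol_par) {
      converged <- TRUE
      break
    }
  }
  s_hat <- par_to_struct(kind, theta[seq_len(ctx$ns)], ctx$nE,
                         envs = ctx$design$envs)
  vR <- theta[ctx$ns + seq_len(ctx$nE)]
  names(vR) <- ctx$design$envs
  cc <- if (length(ctx$cov_locs)) {
    stats::setNames(theta[ctx$ns + ctx$nE + seq_along(ctx$cov_locs)],
                    ctx$cov_locs)
  } else {
    NULL
  }
  blue_cov <- chol2inv(ev$chx)
  dimnames(blue_cov) <- list(colnames(ctx$X), colnames(ctx$X))
  structure(
    list(
      kind = kind,
      structure = s_hat,
      resid_vars = vR,
      resid_cov = cc,
      loglik = ev$loglik,
      converged = converged,
      n_iter = max(trace$iter),
      trace = trace,
      theta = theta,
      blue = stats::setNames(ev$beta, colnames(ctx$X)),
      blue_cov = blue_cov,
      envs = ctx$design$envs,
      ids = ctx$design$ids,
      py_levels = ctx$design$py_levels,
      py_location = data$planting_year_location,
      n_records = ctx$N,
      bend = bend
    ),
    class = "gxe_fit"
  )
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("gxe_fit [", x$kind, "]: logL =", round(x$loglik, 3),
      if (x$converged) "(converged in" else "(NOT converged after",
      x$n_iter, "iterations)\n")
  cat("  environments:", paste(x$envs, collapse = ", "), "\n")
  cat("  residual variances:",
      paste(round(x$resid_vars, 2), collapse = ", "), "\n")
  invisible(x)
}
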