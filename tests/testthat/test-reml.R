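test_that("restricted log-likelihood matches the closed form", {
  ph <- toy_phenotypes(c(1, 2), ids = c("i1", "i2"))
  G <- toy_grm(diag(2) |> `dimnames<-`(list(c("i1", "i2"),
                                            c("i1", "i2"))))
  md <- model_data(ph, G)
  s0 <- env_cov_structure("uniform", sigma2_A = 0)
  ll <- reml_loglik(md, G, s0, resid_vars = 1, bend = 0)
  expect_equal(ll, -0.5 * (log(2 * pi) + log(2) + 0.5), tolerance = 1e-10)
})

test_that("restricted likelihood is invariant to fixed-effect shifts", {
  inst <- random_tiny_instance(31)
  md <- tiny_model_data(inst)
  G <- relationship_matrix(inst$G)
  s <- env_cov_structure("fa1", Lambda = inst$lam, Psi = inst$psi)
  base <- reml_loglik(md, G, s, resid_vars = inst$vR, bend = 0)
  md2 <- md
  md2$y <- md$y + 57.3 # constant lies in the span of the intercept
  expect_equal(reml_loglik(md2, G, s, resid_vars = inst$vR, bend = 0),
               base, tolerance = 1e-9)
})

test_that("likelihood equals the error-contrast oracle on tiny instances", {
  for (seed in 1:25) {
    inst <- random_tiny_instance(seed)
    md <- tiny_model_data(inst)
    G <- relationship_matrix(inst$G)
    nE <- length(inst$envs)
    s <- env_cov_structure("fa1", Lambda = inst$lam, Psi = inst$psi)
    ours <- reml_loglik(md, G, s, resid_vars = inst$vR, bend = 0)
    design <- build_design(md, ids = rownames(G))
    orc <- oracle_reml_loglik(md$y, design$X, design$env_index,
                              design$id_index, inst$G, inst$Sigma,
                              inst$vR)
    expect_equal(ours, as.numeric(orc), tolerance = 1e-8)
  }
})

test_that("single-site fit matches lme4 and a direct two-variance oracle", {
  skip_if_not_installed("lme4")
  set.seed(42)
  n <- 30
  r <- 3
  ids <- sprintf("i%02d", seq_len(n))
  u <- rnorm(n, 0, 2)
  ph <- do.call(rbind, lapply(seq_len(r), function(k) {
    data.frame(Location = "A", Year = "s1", REF_ID = ids,
               Experimental.unit = paste0("A:", ids, ":", k),
               y = 10 + u + rnorm(n), stringsAsFactors = FALSE)
  }))
  class(ph) <- c("phenotype_table", "data.frame")
  G <- diag(n)
  dimnames(G) <- list(ids, ids)
  GA <- relationship_matrix(G)
  md <- model_data(ph, GA)
  fit <- fit_reml(md, GA, kind = "uniform", bend = 0)
  lf <- lme4::lmer(y ~ 1 + (1 | REF_ID), data = ph, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_true(fit$converged)
  expect_equal(fit$structure$sigma2_A, vc$vcov[1], tolerance = 1e-4)
  expect_equal(unname(fit$resid_vars), vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)),
               tolerance = 1e-6)
})

test_that("correlated-relationship fit matches a grid REML oracle", {
  set.seed(8)
  n <- 24
  ids <- sprintf("i%02d", seq_len(n))
  B <- matrix(rnorm(n * n), n)
  G <- crossprod(B) / n + diag(0.3, n)
  G <- G / mean(diag(G))
  dimnames(G) <- list(ids, ids)
  L <- chol(G)
  u <- as.numeric(crossprod(L, rnorm(n))) * 1.5
  ph <- toy_phenotypes(20 + u + rnorm(n, 0, 1), ids)
  GA <- relationship_matrix(G)
  md <- model_data(ph, GA)
  fit <- fit_reml(md, GA, kind = "uniform", bend = 0)
  # independent 2-parameter optimization of the error-contrast likelihood
  design <- build_design(md, ids = rownames(GA))
  obj <- function(par) {
    -oracle_reml_loglik(md$y, design$X, design$env_index,
                        design$id_index, G,
                        matrix(exp(par[1]), 1, 1), exp(par[2]))
  }
  opt <- optim(log(c(1, 1)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(fit$structure$sigma2_A, exp(opt$par[1]), tolerance = 1e-3)
  expect_equal(unname(fit$resid_vars), exp(opt$par[2]), tolerance = 1e-3)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-6)
})

test_that("zero genetic signal pins the additive variance at zero", {
  set.seed(70)
  n <- 40
  ids <- sprintf("i%02d", seq_len(n))
  G <- diag(n)
  dimnames(G) <- list(ids, ids)
  GA <- relationship_matrix(G)
  ph <- do.call(rbind, lapply(1:2, function(k) {
    data.frame(Location = "A", Year = "s1", REF_ID = ids,
               Experimental.unit = paste0("A:", ids, ":", k),
               y = rnorm(n, 50, 1), stringsAsFactors = FALSE)
  }))
  class(ph) <- c("phenotype_table", "data.frame")
  md <- model_data(ph, GA)
  fit <- fit_reml(md, GA, kind = "uniform", bend = 0)
  expect_identical(fit$structure$sigma2_A, 0) # exactly at the boundary
})

test_that("fitted likelihoods respect structure nesting", {
  sh <- small_study()
  f_u <- fit_reml(sh$data, sh$grm, kind = "uniform")
  f_cs <- fit_reml(sh$data, sh$grm, kind = "cs")
  f_fa <- fit_reml(sh$data, sh$grm, kind = "fa1")
  expect_lte(f_u$loglik, f_cs$loglik + 1e-3)
  expect_lte(f_cs$loglik, f_fa$loglik + 1e-3)
  expect_true(f_fa$converged)
})

test_that("both Kronecker layout conventions give the same likelihood", {
  # dense oracle uses Sigma (x) G_A with environment-major u; the fitter
  # never forms the Kronecker product but must agree
  inst <- random_tiny_instance(101)
  md <- tiny_model_data(inst)
  G <- relationship_matrix(inst$G)
  s <- env_cov_structure("fa1", Lambda = inst$lam, Psi = inst$psi)
  ours <- reml_loglik(md, G, s, resid_vars = inst$vR, bend = 0)
  nE <- nrow(inst$Sigma)
  nG <- nrow(inst$G)
  design <- build_design(md, ids = rownames(G))
  # individual-major layout: permutation of the env-major one
  N <- length(md$y)
  Z <- matrix(0, N, nG * nE)
  for (r in seq_len(N)) {
    Z[r, (design$id_index[r] - 1L) * nE + design$env_index[r]] <- 1
  }
  V <- Z %*% kronecker(inst$G, inst$Sigma) %*% t(Z) +
    diag(inst$vR[design$env_index], N)
  p <- ncol(design$X)
  Vi <- solve(V)
  XtViX <- t(design$X) %*% Vi %*% design$X
  P <- Vi - Vi %*% design$X %*% solve(XtViX, t(design$X) %*% Vi)
  ll <- -0.5 * ((N - p) * log(2 * pi) +
                  determinant(V, logarithm = TRUE)$modulus +
                  determinant(XtViX, logarithm = TRUE)$modulus +
                  sum(md$y * (P %*% md$y)))
  expect_equal(ours, as.numeric(ll), tolerance = 1e-8)
})
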