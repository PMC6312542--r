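# Shared fixtures and independent oracles, built in code.

# small phenotype table: n individuals x environments (full factorial),
# ids must match a relationship matrix built with toy_grm()
toy_phenotypes <- function(y, ids, locations = "A", seasons = "s1",
                           planting = NULL) {
  grid <- expand.grid(REF_ID = ids, Location = locations, Year = seasons,
                      stringsAsFactors = FALSE)
  stopifnot(length(y) == nrow(grid))
  d <- data.frame(
    Location = grid$Location, Year = grid$Year, REF_ID = grid$REF_ID,
    Experimental.unit = paste(grid$Location, grid$REF_ID, sep = ":"),
    Planting.date = if (is.null(planting)) NA else planting,
    y = y, stringsAsFactors = FALSE
  )
  class(d) <- c("phenotype_table", "data.frame")
  d
}

toy_grm <- function(M) {
  if (is.null(dimnames(M))) {
    ids <- sprintf("i%02d", seq_len(nrow(M)))
    dimnames(M) <- list(ids, ids)
  }
  relationship_matrix(M)
}

# ---- error-contrast REML oracle -----------------------------------------
# Independent evaluation of the restricted likelihood: build V explicitly
# from a dense Z and Kronecker covariance, form an orthonormal basis K of
# the orthogonal complement of col(X), and evaluate the density of K'y
# (normalized so it matches the standard criterion, which drops the
# constant log|X'X|/2).
oracle_reml_loglik <- function(y, X, env_index, id_index, G_A, Sigma,
                               resid_var_by_env) {
  N <- length(y)
  nG <- nrow(G_A)
  nE <- nrow(Sigma)
  Z <- matrix(0, N, nG * nE)
  for (r in seq_len(N)) {
    Z[r, (env_index[r] - 1L) * nG + id_index[r]] <- 1
  }
  Gfull <- kronecker(Sigma, G_A)
  V <- Z %*% Gfull %*% t(Z) + diag(resid_var_by_env[env_index], N)
  p <- qr(X)$rank
  K <- qr.Q(qr(X), complete = TRUE)[, seq.int(p + 1L, N), drop = FALSE]
  KVK <- t(K) %*% V %*% K
  Ky <- as.numeric(t(K) %*% y)
  -0.5 * ((N - p) * log(2 * pi) +
            determinant(KVK, logarithm = TRUE)$modulus +
            sum(Ky * solve(KVK, Ky)) +
            determinant(crossprod(X), logarithm = TRUE)$modulus)
}

# random tiny REML instance for the oracle-equivalence property
random_tiny_instance <- function(seed) {
  set.seed(seed)
  N <- sample(3:6, 1)
  nG <- sample(2:3, 1)
  nE <- sample(1:2, 1)
  ids <- sprintf("i%d", seq_len(nG))
  envs <- paste0("A", seq_len(nE), ":s1")
  # PD relationship matrix
  B <- matrix(rnorm(nG * nG), nG)
  G <- crossprod(B) / nG + diag(0.5, nG)
  dimnames(G) <- list(ids, ids)
  env_index <- sample(seq_len(nE), N, replace = TRUE)
  env_index[seq_len(nE)] <- seq_len(nE) # every environment observed
  id_index <- sample(seq_len(nG), N, replace = TRUE)
  y <- rnorm(N, 10, 2)
  lam <- runif(nE, 0.3, 1.5)
  psi <- runif(nE, 0.1, 1)
  Sigma <- tcrossprod(lam) + diag(psi, nE)
  vR <- runif(nE, 0.5, 2)
  list(y = y, ids = ids, envs = envs, env_index = env_index,
       id_index = id_index, G = G, Sigma = Sigma, lam = lam, psi = psi,
       vR = vR)
}

# model_data from the raw pieces of a tiny instance
tiny_model_data <- function(inst) {
  loc <- sub(":.*$", "", inst$envs[inst$env_index])
  sea <- sub("^.*:", "", inst$envs[inst$env_index])
  d <- data.frame(
    Location = loc, Year = sea, REF_ID = inst$ids[inst$id_index],
    Experimental.unit = paste0("u", seq_along(inst$y)),
    y = inst$y, stringsAsFactors = FALSE
  )
  class(d) <- c("phenotype_table", "data.frame")
  model_data(d, relationship_matrix(inst$G))
}

# ---- gene-dropping oracle for pedigree relationships ---------------------
# Estimates additive relationships by dropping unique founder alleles
# through the pedigree: A_ij = 2 * P(random allele of i IBD to random
# allele of j), estimated over n_drop independent segregations.
gene_drop_A <- function(ped, n_drop = 1e5, seed = 1) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  p1 <- match(ped$parent1, ids)
  p2 <- match(ped$parent2, ids)
  set.seed(seed)
  a1 <- matrix(0L, n_drop, n) # allele ids per drop x individual
  a2 <- matrix(0L, n_drop, n)
  next_allele <- 0L
  for (i in seq_len(n)) {
    if (is.na(p1[i])) {
      a1[, i] <- next_allele + 1L
      next_allele <- next_allele + 2L
      a2[, i] <- next_allele
    } else {
      pick1 <- runif(n_drop) < 0.5
      a1[, i] <- ifelse(pick1, a1[, p1[i]], a2[, p1[i]])
      pick2 <- runif(n_drop) < 0.5
      a2[, i] <- ifelse(pick2, a1[, p2[i]], a2[, p2[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
        (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
      A[i, j] <- A[j, i] <- 0.5 * mean(ibd)
    }
  }
  A
}

# small simulated study shared by several test files (cached per session)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_G = 160, m = 500,
                        families = list(n_families = 25, size = 3))
      st <- simulate_study(cfg, seed = 421)
      fl <- filter_snps(st$genotypes)
      G <- vanraden_grm(fl$genotypes)
      cache <<- list(cfg = cfg, study = st, grm = G,
                     data = model_data(st$pheno, G,
                                       planting_year_location = "balandran"))
    }
    cache
  }
})
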