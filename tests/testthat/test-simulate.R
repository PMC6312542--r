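test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_G = 60, m = 120,
                    families = list(n_families = 5, size = 2))
  a <- simulate_study(cfg, seed = 5)
  b <- simulate_study(cfg, seed = 5)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$bvs, b$bvs)
  expect_identical(a$pheno$y, b$pheno$y)
  c <- simulate_study(cfg, seed = 6)
  expect_false(identical(a$pheno$y, c$pheno$y))
})

test_that("stored truth reconstructs phenotypes exactly", {
  cfg <- sim_config(n_G = 60, m = 100,
                    families = list(n_families = 4, size = 2))
  st <- simulate_study(cfg, seed = 3)
  tr <- st$truth
  rebuilt <- tr$mean_part + tr$py_part + tr$bv_part + tr$resid_part
  expect_equal(st$pheno$y, rebuilt, tolerance = 1e-12)
})

test_that("overlap design is honoured exactly", {
  cfg <- sim_config(n_G = 110, m = 60, families = NULL)
  st <- simulate_study(cfg, seed = 2)
  counts <- vapply(st$assignment, length, integer(1))
  sets <- strsplit(names(cfg$overlap), "+", fixed = TRUE)
  for (l in cfg$locations) {
    expect_equal(
      unname(counts[l]),
      sum(cfg$overlap[vapply(sets, function(s) l %in% s, logical(1))])
    )
  }
  # individuals present everywhere
  common <- Reduce(intersect, st$assignment)
  expect_equal(length(common),
               unname(cfg$overlap["balandran+bourran+forli+prosser"]))
})

test_that("LD decays with distance and vanishes in the short-decay limit", {
  cfg <- sim_config(n_G = 300, m = 400, n_ancestors = 300,
                    families = NULL)
  sim <- simulate_genotypes(cfg, seed = 31, n = 300)
  keep <- filter_snps(sim$genotypes, min_maf = 0.05)
  lp <- ld_pairs(keep$genotypes, max_distance = 2e6)
  bins <- bin_ld(lp$pairs, bin_size = 400)
  expect_lt(cor(bins$mean_distance, bins$mean_r2, method = "spearman"), 0)
  expect_gt(bins$mean_r2[1], bins$mean_r2[nrow(bins)])

  cfg0 <- sim_config(n_G = 300, m = 400, ld_decay_bp = 1,
                     n_ancestors = 300, families = NULL)
  sim0 <- simulate_genotypes(cfg0, seed = 31, n = 300)
  keep0 <- filter_snps(sim0$genotypes, min_maf = 0.05)
  adj <- ld_pairs(keep0$genotypes, max_distance = 1e5)$pairs
  expect_lt(mean(adj$r2), 0.05)
})

test_that("families show Mendelian relatedness in the GRM", {
  cfg <- sim_config(n_G = 220, m = 1200, n_ancestors = 220,
                    families = list(n_families = 10, size = 6))
  st <- simulate_study(cfg, seed = 17)
  keep <- filter_snps(st$genotypes, min_maf = 0.05)
  G <- vanraden_grm(keep$genotypes)
  ped <- st$pedigree
  off <- ped[!is.na(ped$parent1) & grepl("^o", ped$id), ]
  sib_vals <- c()
  po_vals <- c()
  for (fam in split(off, paste(off$parent1, off$parent2))) {
    ids <- fam$id
    if (length(ids) >= 2) {
      pr <- t(combn(ids, 2))
      sib_vals <- c(sib_vals, G[pr])
    }
    po_vals <- c(po_vals, G[cbind(ids, fam$parent1[1])])
  }
  expect_lt(abs(mean(sib_vals) - 0.5), 0.07)
  expect_lt(abs(mean(po_vals) - 0.5), 0.07)
})

test_that("simulated pedigree agrees with the gene-dropping oracle", {
  cfg <- sim_config(n_G = 10, m = 40, n_ancestors = 4,
                    families = list(n_families = 2, size = 2))
  st <- simulate_study(cfg, seed = 9)
  A <- pedigree_A(st$pedigree)
  A_mc <- gene_drop_A(st$pedigree, n_drop = 1e5, seed = 2)
  expect_lt(max(abs(A - A_mc[rownames(A), colnames(A)])), 0.02)
})

test_that("breeding values realize the target covariance structure", {
  cfg <- sim_config(n_G = 500, m = 2000, n_ancestors = 500,
                    families = NULL)
  sim <- simulate_genotypes(cfg, seed = 13, n = 500)
  bv <- simulate_true_bvs(sim$genotypes, cfg$structure,
                          target_vG = as.numeric(cfg$vG), seed = 13)
  realized <- cor(bv)
  target <- implied_env_correlations(cfg$structure)
  expect_lt(max(abs(realized - target)), 0.05)
  # rank-1 structure: identical environments up to scale
  s1 <- env_cov_structure("fa1", Lambda = c(1, 1), Psi = c(0, 0),
                          envs = c("a", "b"))
  bv1 <- simulate_true_bvs(sim$genotypes, s1, target_vG = c(2, 8),
                           seed = 5)
  expect_equal(cor(bv1[, 1], bv1[, 2]), 1, tolerance = 1e-10)
  expect_equal(var(bv1[, 2]) / var(bv1[, 1]), 4, tolerance = 1e-10)
})

test_that("per-environment phenotypic variance is near vG + vR", {
  cfg <- sim_config(n_G = 400, m = 800, planting_year = NULL)
  st <- simulate_study(cfg, seed = 23)
  md <- st$pheno
  for (e in c("bourran:s1", "prosser:s2")) {
    sel <- paste(md$Location, md$Year, sep = ":") == e
    vP <- var(md$y[sel])
    target <- unname(cfg$vG[e] + cfg$vR[e])
    expect_lt(abs(vP - target) / target, 0.35)
  }
})

test_that("recovery reports round-trip through JSON losslessly", {
  sh <- small_study()
  fit <- fit_reml(sh$data, sh$grm, kind = "fa1")
  rep <- truth_vs_estimate_report(sh$study, fit)
  f <- tempfile(fileext = ".json")
  write_recovery_report(rep, f)
  back <- read_recovery_report(f)
  expect_equal(back$h2$bias, rep$h2$bias, tolerance = 1e-12)
  expect_equal(back$correlation_error, rep$correlation_error,
               tolerance = 1e-12)
  unlink(f)
})

test_that("truth compared to itself reports zero bias", {
  sh <- small_study()
  cfg <- sh$cfg
  perfect <- structure(list(
    kind = "fa1", structure = cfg$structure,
    resid_vars = cfg$vR, envs = cfg$envs, converged = TRUE
  ), class = "gxe_fit")
  rep <- truth_vs_estimate_report(sh$study, perfect)
  expect_equal(max(abs(rep$h2$bias)), 0)
  expect_equal(max(abs(rep$correlation_error)), 0)
})
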