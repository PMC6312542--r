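# Cross-validation behaviour on small two-location designs (the full-size
# behavioural checks live in the acceptance suite).

cv_fixture <- function(seed = 29, n_G = 120, m = 400, vR = NULL) {
  cfg <- sim_config(
    n_G = n_G, m = m,
    locations = c("north", "south"), seasons = c("s1", "s2"),
    overlap = c("north+south" = n_G), # everyone everywhere
    vG = c(60, 55, 50, 45), vR = vR %||% c(15, 15, 15, 15),
    common_frac = c(0.95, 0.95, 0.9, 0.9),
    env_means = c(150, 152, 160, 161),
    obs_prob = rep(1, 4),
    planting_year = NULL,
    families = list(n_families = 15, size = 4),
    n_ancestors = 12
  )
  st <- simulate_study(cfg, seed = seed)
  keep <- filter_snps(st$genotypes, min_maf = 0.05)
  G <- vanraden_grm(keep$genotypes)
  md <- model_data(st$pheno, G)
  fit <- fit_reml(md, G, kind = "fa1")
  list(cfg = cfg, study = st, grm = G, data = md, fit = fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("within-location CV produces coherent accuracy tables", {
  fx <- cv_fixture()
  suppressWarnings(
    cv <- within_location_cv(fx$data, fx$grm, fx$fit, k = 5, seed = 1)
  )
  res <- cv$results
  expect_setequal(res$location, c("north", "south"))
  expect_equal(nrow(res), 4L) # 2 locations x 2 seasons
  h2 <- heritability_table(fx$fit)
  for (i in seq_len(nrow(res))) {
    env <- paste(res$location[i], res$season[i], sep = ":")
    expect_equal(res$PACC[i] * sqrt(h2$h2[h2$env == env]), res$PA[i],
                 tolerance = 1e-12)
    expect_equal(res$se.PACC[i], 1 / sqrt(res$n_GxLS[i]))
  }
  # with everyone at both locations and high h2, prediction works
  expect_gt(mean(res$PA), 0.4)
  # folds carry one row per location-set-season
  expect_equal(nrow(cv$folds), 2 * 5 * 2)
})

test_that("fold assignment is reproducible and seed-sensitive", {
  fx <- cv_fixture()
  suppressWarnings({
    a <- within_location_cv(fx$data, fx$grm, fx$fit, k = 5, seed = 4)
    b <- within_location_cv(fx$data, fx$grm, fx$fit, k = 5, seed = 4)
    c <- within_location_cv(fx$data, fx$grm, fx$fit, k = 5, seed = 5)
  })
  expect_equal(a$results$PA, b$results$PA)
  expect_false(isTRUE(all.equal(a$results$PA, c$results$PA)))
})

test_that("leave-location-out predicts from the preserved locations", {
  fx <- cv_fixture()
  suppressWarnings(
    cv <- leave_location_out_cv(fx$data, fx$grm, fx$fit)
  )
  res <- cv$results
  expect_equal(nrow(res), 4L)
  # identical individuals at both locations and high genetic correlation:
  # across-location prediction must carry real signal
  expect_gt(mean(res$PA), 0.4)
  expect_equal(res$n_GxL, rep(120, 4))
})

test_that("unrelated validation individuals cannot be predicted across
           locations", {
  fx <- cv_fixture()
  # disjoint design: individuals at exactly one location, unrelated panel
  cfg <- sim_config(
    n_G = 120, m = 400,
    locations = c("north", "south"), seasons = c("s1", "s2"),
    overlap = c("north" = 60, "south" = 60),
    vG = c(60, 55, 50, 45), vR = rep(15, 4),
    common_frac = c(0.95, 0.95, 0.9, 0.9),
    env_means = c(150, 152, 160, 161), obs_prob = rep(1, 4),
    planting_year = NULL, families = NULL, n_ancestors = 120
  )
  st <- simulate_study(cfg, seed = 41)
  keep <- filter_snps(st$genotypes, min_maf = 0.05)
  G <- vanraden_grm(keep$genotypes)
  md <- model_data(st$pheno, G)
  fit <- fit_reml(md, G, kind = "fa1")
  suppressWarnings(cv <- leave_location_out_cv(md, G, fit))
  expect_lt(mean(abs(cv$results$PA)), 0.3) # centred on zero
})
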