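mk_geno <- function(m, ids = NULL, loci = NULL) {
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(nrow(m)))
  if (is.null(loci)) loci <- sprintf("l%02d", seq_len(ncol(m)))
  dimnames(m) <- list(ids, loci)
  genotype_matrix(m)
}

test_that("allele frequencies count alternate-allele dosage", {
  expect_equal(unname(allele_frequencies(mk_geno(cbind(c(0, 2))))), 0.5)
  expect_equal(unname(allele_frequencies(mk_geno(cbind(c(2, 2, 2))))), 1.0)
  expect_equal(unname(allele_frequencies(mk_geno(cbind(c(0, 1, 2, 1))))),
               0.5)
})

test_that("VanRaden method 1 GRM matches hand evaluation", {
  g <- mk_geno(rbind(c(0, 2), c(2, 0)))
  G <- vanraden_grm(g, p = c(0.5, 0.5))
  expect_equal(unclass(G), rbind(c(2, -2), c(-2, 2)),
               ignore_attr = TRUE)
  g2 <- mk_geno(rbind(c(1, 1), c(1, 1)))
  G2 <- vanraden_grm(g2, p = c(0.5, 0.5))
  expect_equal(max(abs(G2)), 0)
})

test_that("GRM rows sum to zero under observed-frequency centering", {
  set.seed(7)
  m <- matrix(sample(0:2, 30 * 50, replace = TRUE), 30, 50)
  g <- mk_geno(m)
  G <- vanraden_grm(g)
  expect_lt(max(abs(rowSums(G))), 1e-8)
  expect_lt(max(abs(G - t(G))), 1e-12)
})

test_that("monomorphic or degenerate panels are rejected", {
  expect_error(vanraden_grm(mk_geno(rbind(c(0, 0), c(0, 2)))),
               "monomorphic")
})

test_that("mean GRM diagonal is ~1 on a large unrelated panel", {
  cfg <- sim_config(n_G = 500, m = 2000, n_ancestors = 500,
                    families = NULL)
  sim <- simulate_genotypes(cfg, seed = 99, n = 500)
  keep <- filter_snps(sim$genotypes, min_maf = 0.01)
  G <- vanraden_grm(keep$genotypes)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("relationship summaries use the population variance", {
  s <- relationship_summary(toy_grm(diag(2)))
  expect_equal(s$diag$var, 0)
  expect_equal(s$offdiag$var, 0)
  s2 <- relationship_summary(toy_grm(rbind(c(1, 0), c(0, 2))))
  expect_equal(s2$diag$var, 0.25)
  # invariance to relabelling
  M <- matrix(c(1.2, 0.3, 0.1, 0.3, 0.9, 0, 0.1, 0, 1.1), 3)
  perm <- c(3, 1, 2)
  s3 <- relationship_summary(toy_grm(M))
  s4 <- relationship_summary(toy_grm(M[perm, perm]))
  expect_equal(s3$diag$var, s4$diag$var)
  expect_equal(s3$offdiag$var, s4$offdiag$var)
})

test_that("individual-by-location expansion is M G M'", {
  G1 <- toy_grm(matrix(1, 1, 1))
  C1 <- individual_by_location_grm(
    G1, data.frame(id = "i01", location = c("A", "B"))
  )
  expect_equal(unclass(C1), matrix(1, 2, 2), ignore_attr = TRUE)
  # disjoint assignment of unrelated individuals is a permutation
  G2 <- toy_grm(diag(2))
  C2 <- individual_by_location_grm(
    G2, data.frame(id = c("i01", "i02"), location = c("A", "B"))
  )
  expect_equal(unclass(C2), diag(2), ignore_attr = TRUE)
  # trace identity
  M <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  G3 <- toy_grm(M)
  asn <- data.frame(id = c("i01", "i01", "i02", "i03", "i04", "i04"),
                    location = c("A", "B", "A", "B", "A", "B"))
  C3 <- individual_by_location_grm(G3, asn)
  expect_equal(sum(diag(C3)),
               sum(diag(M)[match(asn$id, rownames(G3))]))
  expect_error(
    individual_by_location_grm(G3, data.frame(id = "nope", location = "A")),
    "unknown individual"
  )
})

test_that("eigen-ordination fractions behave", {
  o <- eigen_ordination(toy_grm(diag(4)), k = 2)
  expect_equal(o$fraction, c(0.25, 0.25))
  v <- c(1, 2, 3)
  R <- toy_grm(tcrossprod(v))
  expect_equal(eigen_ordination(R, k = 1)$fraction, 1)
  o2 <- eigen_ordination(toy_grm(rbind(c(2, 1), c(1, 2))), k = 1)
  expect_equal(o2$values[1], 3)
  expect_equal(o2$fraction, 0.75)
  # non-increasing fractions
  set.seed(2)
  M <- crossprod(matrix(rnorm(36), 6))
  fr <- eigen_ordination(toy_grm(M), k = 6)$fraction
  expect_true(all(diff(fr) <= 1e-12))
})
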