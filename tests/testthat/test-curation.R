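mk_set <- function(m, ids, loci) {
  dimnames(m) <- list(ids, loci)
  genotype_matrix(m, map = data.frame(locus = loci, chrom = "1",
                                      pos_bp = seq_along(loci) * 1000))
}

test_that("merging keeps agreements, fills singletons, voids conflicts", {
  a <- mk_set(matrix(c(0, 0, NA, 1), 2, 2), c("x", "y"), c("l1", "l2"))
  b <- mk_set(matrix(c(0, 2, 2, 1), 2, 2), c("x", "y"), c("l1", "l2"))
  m <- merge_genotype_sources(list(A = a, B = b))
  d <- m$genotypes$dosages
  expect_equal(d["x", "l1"], 0)        # agreement retained
  expect_true(is.na(d["y", "l1"]))     # (0, 2) conflict set to missing
  expect_equal(d["x", "l2"], 2)        # single-source call fills the cell
  expect_equal(d["y", "l2"], 1)
  expect_equal(nrow(m$conflicts), 1L)
  expect_equal(m$conflicts$id, "y")
})

test_that("merging is order-insensitive", {
  set.seed(3)
  sets <- lapply(1:3, function(k) {
    m <- matrix(sample(c(0, 1, 2, NA), 12, replace = TRUE), 3, 4)
    mk_set(m, c("x", "y", "z"), paste0("l", 1:4))
  })
  m1 <- merge_genotype_sources(sets)
  m2 <- merge_genotype_sources(rev(sets))
  expect_identical(m1$genotypes$dosages, m2$genotypes$dosages)
  expect_equal(nrow(m1$conflicts), nrow(m2$conflicts))
})

test_that("merging requires shared loci between sources", {
  a <- mk_set(matrix(0, 1, 2), "x", c("l1", "l2"))
  b <- mk_set(matrix(0, 1, 2), "x", c("l3", "l4"))
  expect_error(merge_genotype_sources(list(a, b)), "merge error")
})

test_that("SNP filters remove by missingness and MAF and reconcile", {
  d <- rbind(rep(0, 4), c(0, 1, NA, 1), c(0, 2, NA, 1), c(0, 1, NA, 0),
             c(0, 1, NA, 1), c(0, 1, NA, 1), c(0, 1, 2, 1), c(0, 1, 2, 0),
             c(0, 1, 2, 1), c(0, 1, 2, 1))
  g <- mk_set(d, sprintf("i%02d", 1:10), paste0("l", 1:4))
  out <- filter_snps(g, max_missing = 0.30, min_maf = 0.05)
  # l1 monomorphic (MAF 0) -> removed; l2 polymorphic complete -> kept
  # l3 has 5/10 missing (>30%) -> removed; l4 MAF 0.35 -> kept
  expect_equal(colnames(out$genotypes$dosages), c("l2", "l4"))
  rep <- out$report
  expect_equal(rep$n_loci_in,
               rep$n_removed_missing + rep$n_removed_maf + rep$n_retained)
  # retained dosages unchanged, individual order unchanged
  expect_identical(out$genotypes$dosages[, "l2"], g$dosages[, "l2"])
  expect_identical(rownames(out$genotypes$dosages), rownames(g$dosages))
})

test_that("a locus with exactly threshold missingness is retained", {
  d <- cbind(c(NA, NA, NA, 1, 1, 0, 1, 2, 1, 1)) # 30% missing, MAF 0.29
  g <- mk_set(d, sprintf("i%02d", 1:10), "l1")
  out <- filter_snps(g, max_missing = 0.30, min_maf = 0.05)
  expect_equal(out$report$n_retained, 1L)
})

test_that("all-removed panels warn rather than error", {
  g <- mk_set(matrix(0, 4, 2), paste0("i", 1:4), c("l1", "l2"))
  expect_warning(filter_snps(g), "empty panel")
})

test_that("duplicate profiles group by concordance, transitively", {
  base <- sample(c(0, 1, 2), 1000, replace = TRUE)
  near <- base; near[1] <- (near[1] + 1) %% 3    # 999/1000 concordant
  far <- base; far[1:100] <- (far[1:100] + 1) %% 3 # 900/1000
  d <- rbind(base, base, near, far)
  g <- mk_set(d, c("a", "b", "c", "d"), sprintf("l%04d", 1:1000))
  dup <- find_duplicate_profiles(g, min_overlap = 100, concordance = 0.99)
  expect_equal(length(dup$groups), 1L)
  expect_setequal(dup$groups[[1]], c("a", "b", "c")) # transitive via 'a'
  expect_false("d" %in% unlist(dup$groups))
  expect_equal(dup$representatives, "a")
  expect_setequal(dup$keep, c("a", "d"))
})

test_that("pairs with insufficient overlap are skipped and logged", {
  d <- rbind(c(0, 1, rep(NA, 8)), c(0, 1, rep(NA, 8)),
             c(NA, NA, 0, 1, 2, 0, 1, 2, 0, 1))
  g <- mk_set(d, c("a", "b", "c"), paste0("l", 1:10))
  dup <- find_duplicate_profiles(g, min_overlap = 5, concordance = 0.99)
  expect_equal(length(dup$groups), 0L) # a-b overlap only 2 loci
  expect_true(nrow(dup$skipped_pairs) >= 1L)
})

test_that("imputation fills by flanking match, is seeded, and errors on
           all-missing loci", {
  # complete panel: flanking pattern (l1, l3) = (0, 2) always has l2 = 2
  d <- rbind(c(0, 2, 2), c(0, 2, 2), c(0, 2, 2), c(2, 0, 0), c(0, NA, 2))
  g <- mk_set(d, paste0("i", 1:5), c("l1", "l2", "l3"))
  out <- impute_missing(g, seed = 1)
  expect_equal(out$genotypes$dosages["i5", "l2"], 2)
  expect_equal(out$report$n_imputed, 1L)
  expect_equal(out$report$n_flanking, 1L)

  complete <- mk_set(d[1:4, ], paste0("i", 1:4), c("l1", "l2", "l3"))
  expect_identical(impute_missing(complete, seed = 9)$genotypes$dosages,
                   complete$dosages)

  allmiss <- mk_set(cbind(c(0, 1), c(NA, NA)), c("a", "b"), c("l1", "l2"))
  expect_error(impute_missing(allmiss), "all calls missing")
})

test_that("different seeds change only originally-missing cells", {
  set.seed(5)
  d <- matrix(sample(c(0, 1, 2), 200, replace = TRUE), 20, 10)
  miss <- matrix(runif(200) < 0.15, 20, 10)
  d[miss] <- NA
  g <- mk_set(d, sprintf("i%02d", 1:20), sprintf("l%02d", 1:10))
  a <- impute_missing(g, seed = 1)$genotypes$dosages
  b <- impute_missing(g, seed = 2)$genotypes$dosages
  expect_false(anyNA(a))
  expect_identical(a[!miss], b[!miss])
  expect_identical(a[!miss], d[!miss])
  # determinism
  expect_identical(a, impute_missing(g, seed = 1)$genotypes$dosages)
})
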