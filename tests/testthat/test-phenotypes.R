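test_that("wide season columns reshape to one record per observation", {
  src <- data.frame(
    cultivar = c("Bing", "Lapins"), site = "Balandran",
    y1997 = c(150, 160), y1998 = c(152, 158),
    note = c("a", "b"), stringsAsFactors = FALSE
  )
  out <- standardize_phenotypes(
    src,
    field_map = c(REF_ID = "cultivar", Location = "site"),
    year_columns = c("1997" = "y1997", "1998" = "y1998")
  )
  expect_s3_class(out, "phenotype_table")
  expect_equal(nrow(out), 4L)
  expect_setequal(out$Year, c("1997", "1998"))
  expect_equal(sort(unique(out$REF_ID)), c("bing", "lapins"))
  expect_equal(out$note, rep(c("a", "b"), 2)) # unmapped column kept
  expect_equal(out$y[out$REF_ID == "bing" & out$Year == "1997"], 150)
})

test_that("optional design fields stay empty but records are kept", {
  src <- data.frame(id = "Bing", loc = "A", yr = 1997, val = 151)
  out <- standardize_phenotypes(
    src, field_map = c(REF_ID = "id", Location = "loc", Year = "yr",
                       y = "val")
  )
  expect_equal(nrow(out), 1L)
  expect_true(is.na(out$Block))
  expect_true(is.na(out$Plot))
  expect_true(all(phenotype_fields() %in% names(out)))
})

test_that("schema violations error clearly", {
  src <- data.frame(id = "Bing", loc = "A", yr = 1997, val = 151)
  expect_error(
    standardize_phenotypes(src, field_map = c(REF_ID = "id", y = "val")),
    "schema error"
  )
  dup <- data.frame(id = c("Bing", "Bing"), loc = "A", yr = 1997,
                    val = c(151, 152))
  expect_error(
    standardize_phenotypes(
      dup, field_map = c(REF_ID = "id", Location = "loc", Year = "yr",
                         y = "val")
    ),
    "duplicate observation"
  )
})

test_that("REF_IDs resolve through the dictionary", {
  d <- name_dictionary(c("Bing Cherry"), final = "bing")
  src <- data.frame(id = "BING CHERRY", loc = "A", yr = 2000, val = 100)
  out <- standardize_phenotypes(
    src, field_map = c(REF_ID = "id", Location = "loc", Year = "yr",
                       y = "val"),
    dictionary = d
  )
  expect_equal(out$REF_ID, "bing")
})

test_that("phenotype CSV round-trips with extra columns", {
  ph <- toy_phenotypes(c(1.5, 2.5), c("i1", "i2"))
  ph$extra <- c("p", "q")
  f <- tempfile(fileext = ".csv")
  write_phenotype_csv(ph, f)
  back <- read_phenotype_csv(f)
  expect_equal(back$y, ph$y)
  expect_equal(back$REF_ID, ph$REF_ID)
  expect_equal(back$extra, ph$extra)
  unlink(f)
})

test_that("genotype CSV and ped/map readers agree on dosages", {
  d <- rbind(c(0, 1, 2), c(2, 1, 0))
  dimnames(d) <- list(c("a", "b"), c("l1", "l2", "l3"))
  g <- genotype_matrix(d, map = data.frame(
    locus = c("l1", "l2", "l3"), chrom = c("1", "1", "2"),
    pos_bp = c(100, 5000, 30)
  ))
  fg <- tempfile(fileext = ".csv")
  fm <- tempfile(fileext = ".csv")
  write_genotype_csv(g, fg, fm)
  back <- read_genotype_csv(fg, fm)
  expect_equal(back$dosages, g$dosages)
  expect_equal(back$map$chrom, g$map$chrom)
  unlink(c(fg, fm))

  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("1 l1 0 100", "1 l2 0.5 5000", "2 l3 0 30"), map)
  # dosage counts the alphabetically later allele (B); '0 0' is missing
  writeLines(c("f a 0 0 0 -9 A A A B B B",
               "f b 0 0 0 -9 B B A B 0 0"), ped)
  gp <- read_plink(ped, map)
  expect_equal(unname(gp$dosages["a", ]), c(0, 1, 2))
  expect_equal(unname(gp$dosages["b", c("l1", "l2")]), c(2, 1))
  expect_true(is.na(gp$dosages["b", "l3"]))
  expect_equal(gp$map$pos_cm, c(0, 0.5, 0))
  unlink(c(ped, map))
})
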