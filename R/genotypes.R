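# Genotype dosage matrices with locus maps.
#
# Dosages are counted copies of the alternate allele, so each cell is in
# {0, 1, 2, NA}. Rows are individuals (keyed by final name), columns are
# loci; the locus map carries chromosome, physical position (bp, 1-based)
# and optionally genetic position (cM).

#' Construct a genotype matrix
#'
#' @param dosages Numeric matrix (individuals x loci) with entries in
#'   `{0, 1, 2, NA}`; dimnames are individual and locus labels.
#' @param map Data.frame with one row per locus: `locus`, `chrom`, `pos_bp`
#'   and optionally `pos_cm`. Defaults to a single-chromosome map with unit
#'   spacing (useful for toy matrices without physical context).
#' @return An object of class `genotype_matrix`: a list with `dosages`
#'   (numeric matrix) and `map`.
#' @export
genotype_matrix <- function(dosages, map = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosages)) && nrow(dosages) > 0L) {
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages)) && ncol(dosages) > 0L) {
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  }
  if (anyDuplicated(rownames(dosages))) stop("duplicate individual labels")
  if (anyDuplicated(colnames(dosages))) stop("duplicate locus labels")
  if (is.null(map)) {
    map <- data.frame(
      locus = colnames(dosages) %||% character(),
      chrom = rep("1", ncol(dosages)),
      pos_bp = seq_len(ncol(dosages)),
      stringsAsFactors = FALSE
    )
  }
  map <- as.data.frame(map)
  need <- c("locus", "chrom", "pos_bp")
  if (!all(need %in% names(map))) {
    stop("map must have columns: ", paste(need, collapse = ", "))
  }
  map$locus <- as.character(map$locus)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  if (any(map$pos_bp < 0)) stop("positions must be non-negative")
  if (!identical(map$locus, colnames(dosages))) {
    m <- match(colnames(dosages), map$locus)
    if (anyNA(m)) stop("map is missing loci: ",
                       paste(colnames(dosages)[is.na(m)][1:5], collapse = ", "))
    map <- map[m, , drop = FALSE]
  }
  if (anyDuplicated(map[, c("chrom", "pos_bp", "locus")])) {
    stop("duplicate (chromosome, position, name) in map")
  }
  rownames(map) <- NULL
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "genotype_matrix:", nrow(x$dosages), "individuals x",
    ncol(x$dosages), "loci;",
    sum(is.na(x$dosages)), "missing calls;",
    length(unique(x$map$chrom)), "chromosome(s)\n"
  )
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read a genotype matrix from CSV
#'
#' Expects rows = individuals (first column = individual label), columns =
#' loci, cells in 0/1/2/NA. An optional map CSV supplies `locus`, `chrom`,
#' `pos_bp` (and `pos_cm`).
#'
#' @param file Path to the dosage CSV.
#' @param map_file Optional path to the locus map CSV.
#' @return A [genotype_matrix()].
#' @export
read_genotype_csv <- function(file, map_file = NULL) {
  d <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  map <- if (!is.null(map_file)) {
    utils::read.csv(map_file, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  genotype_matrix(m, map)
}

#' Write a genotype matrix to CSV
#'
#' @param G A [genotype_matrix()].
#' @param file Output path for the dosage CSV.
#' @param map_file Optional output path for the locus map CSV.
#' @return Invisibly, `file`.
#' @export
write_genotype_csv <- function(G, file, map_file = NULL) {
  d <- data.frame(id = rownames(G$dosages), G$dosages,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, file, row.names = FALSE)
  if (!is.null(map_file)) utils::write.csv(G$map, map_file, row.names = FALSE)
  invisible(file)
}

#' Read PLINK-style ped/map files as a genotype matrix
#'
#' The map file gives chromosome, locus name, genetic position (cM) and
#' physical position (bp), whitespace-separated. The ped file carries family
#' id, individual id, parents, sex and phenotype in columns 1-6 and allele
#' pairs from column 7 on; `0` denotes a missing allele. Allele pairs are
#' recoded to dosages as the count of the alphabetically later allele
#' observed at the locus (a deterministic convention recorded in the map as
#' `counted_allele`).
#'
#' @param ped_file Path to the .ped file.
#' @param map_file Path to the .map file.
#' @return A [genotype_matrix()] whose map includes `pos_cm` and
#'   `counted_allele`.
#' @export
read_plink <- function(ped_file, map_file) {
  map_raw <- utils::read.table(map_file, stringsAsFactors = FALSE)
  if (ncol(map_raw) < 4L) stop("map file needs 4 columns: chrom, locus, cM, bp")
  names(map_raw)[1:4] <- c("chrom", "locus", "pos_cm", "pos_bp")
  ped <- utils::read.table(ped_file, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map_raw)
  if (ncol(ped) != 6L + 2L * m) {
    stop("ped file has ", ncol(ped), " columns; expected ", 6L + 2L * m,
         " for ", m, " loci")
  }
  ids <- ped[[2L]]
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  dos <- matrix(NA_real_, nrow(ped), m, dimnames = list(ids, map_raw$locus))
  counted <- character(m)
  for (j in seq_len(m)) {
    alleles <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(alleles) > 2L) {
      stop("locus ", map_raw$locus[j], " has >2 alleles")
    }
    counted[j] <- if (length(alleles)) alleles[length(alleles)] else NA_character_
    if (length(alleles)) {
      dos[, j] <- (a1[, j] == counted[j]) + (a2[, j] == counted[j])
    }
  }
  map <- data.frame(
    locus = map_raw$locus, chrom = as.character(map_raw$chrom),
    pos_bp = as.numeric(map_raw$pos_bp), pos_cm = as.numeric(map_raw$pos_cm),
    counted_allele = counted, stringsAsFactors = FALSE
  )
  genotype_matrix(dos, map)
}
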