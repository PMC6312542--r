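# Genomic and derived relationship matrices.

#' Observed alternate-allele frequencies
#'
#' @param G A complete (imputed) [genotype_matrix()].
#' @return Named numeric vector `p` with `p[j] = sum(dosage_j) / (2 n)`.
#' @export
allele_frequencies <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  if (nrow(d) == 0L || ncol(d) == 0L) stop("empty genotype matrix")
  if (anyNA(d)) stop("allele frequencies require a complete (imputed) matrix")
  colMeans(d) / 2
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers dosages by twice the allele frequency and scales the
#' cross-product by `2 * sum(p * (1 - p))`:
#' `G_A = Z Z' / (2 sum p_j (1 - p_j))` with `Z = M - 2p`. With observed
#' allele frequencies every row of `G_A` sums to zero by construction.
#'
#' @param G A complete [genotype_matrix()].
#' @param p Allele frequency vector; defaults to [allele_frequencies()] of
#'   `G`. Loci fixed at `p = 0` or `1` are rejected (filter first).
#' @return A symmetric matrix of class `relationship_matrix` with attribute
#'   `kind = "genomic"`.
#' @export
vanraden_grm <- function(G, p = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  if (anyNA(d)) stop("GRM requires a complete (imputed) matrix")
  if (is.null(p)) p <- allele_frequencies(G)
  stopifnot(length(p) == ncol(d))
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic loci present (p = 0 or 1); filter before computing GRM")
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("degenerate panel: sum p(1-p) is zero")
  Z <- sweep(d, 2L, 2 * p, `-`)
  A <- tcrossprod(Z) / denom
  A <- (A + t(A)) / 2
  relationship_matrix(A, kind = "genomic")
}

#' Construct a relationship matrix object
#'
#' @param values Symmetric numeric matrix with individual labels as
#'   dimnames.
#' @param kind One of `"genomic"`, `"pedigree"`, `"individual_by_location"`.
#' @return The matrix with class `relationship_matrix` and a `kind`
#'   attribute.
#' @export
relationship_matrix <- function(values,
                                kind = c("genomic", "pedigree",
                                         "individual_by_location")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  check_symmetric(values, what = "relationship matrix")
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("ind", seq_len(nrow(values)))
  }
  structure(values, kind = kind, class = c("relationship_matrix", "matrix"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("relationship_matrix (", attr(x, "kind"), "): ",
      nrow(x), " x ", ncol(x),
      "; mean diagonal ", round(mean(diag(x)), 3), "\n", sep = "")
  invisible(x)
}

#' Bend a relationship matrix to positive definiteness
#'
#' Adds `epsilon` to the diagonal before inversion-heavy steps; a GRM with
#' fewer markers than individuals, or with clonal duplicates, is singular.
#'
#' @param R A `relationship_matrix` (or plain symmetric matrix).
#' @param epsilon Diagonal offset.
#' @return The bent matrix (class preserved).
#' @export
bend_matrix <- function(R, epsilon = 1e-6) {
  R + diag(epsilon, nrow(R))
}

#' Summary of relationship-coefficient distributions
#'
#' Diagonal and strictly-upper-triangle entries are summarized separately;
#' variances use the population convention (divide by the count).
#'
#' @param R A `relationship_matrix`.
#' @param breaks Histogram breaks passed to [graphics::hist()] machinery via
#'   [base::cut()]; default 30 equal-width bins.
#' @return A list with `diag` and `offdiag`, each holding `mean`, `var`
#'   (population), `mode` (midpoint of the most populated histogram bin),
#'   `max`, and `hist` (data.frame of bin midpoints and counts).
#' @export
relationship_summary <- function(R, breaks = 30) {
  stopifnot(nrow(R) >= 2L)
  dg <- diag(R)
  od <- R[upper.tri(R)]
  one <- function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(
      mean = mean(x), var = pop_var(x),
      mode = h$mids[which.max(h$counts)], max = max(x),
      hist = data.frame(mid = h$mids, count = h$counts)
    )
  }
  list(diag = one(dg), offdiag = one(od))
}

#' Individual-by-location relationship matrix
#'
#' Expands a GRM to one row per (individual, location) realisation:
#' `C = M G_A M'` where `M` is the 0/1 incidence of realisations onto
#' individuals.
#'
#' @param G_A A `relationship_matrix` over individuals.
#' @param assignments Data.frame with columns `id` and `location`, one row
#'   per realisation.
#' @return A `relationship_matrix` of kind `individual_by_location` with
#'   labels `id:location`.
#' @export
individual_by_location_grm <- function(G_A, assignments) {
  stopifnot(all(c("id", "location") %in% names(assignments)))
  idx <- match(as.character(assignments$id), rownames(G_A))
  if (anyNA(idx)) {
    stop("assignment references unknown individual(s): ",
         paste(unique(assignments$id[is.na(idx)])[1:5], collapse = ", "))
  }
  C <- G_A[idx, idx, drop = FALSE]
  lab <- paste(assignments$id, assignments$location, sep = ":")
  dimnames(C) <- list(lab, lab)
  relationship_matrix(unclass(C), kind = "individual_by_location")
}

#' Eigen-ordination of a relationship matrix
#'
#' Top-k eigenpairs with the fraction of variation explained. The default
#' denominator is the sum of positive eigenvalues; `denominator = "trace"`
#' uses `trace(R)` instead.
#'
#' @param R Symmetric `relationship_matrix`.
#' @param k Number of leading components to return.
#' @param denominator `"positive"` (default) or `"trace"`.
#' @return A list with `values` (all eigenvalues, descending), `vectors`
#'   (n x k), and `fraction` (length-k fractions of variation explained).
#' @export
eigen_ordination <- function(R, k = 2, denominator = c("positive", "trace")) {
  denominator <- match.arg(denominator)
  check_symmetric(unclass(R), what = "ordination input")
  stopifnot(k >= 1, k <= nrow(R))
  e <- eigen((unclass(R) + t(unclass(R))) / 2, symmetric = TRUE)
  denom <- switch(denominator,
    positive = sum(e$values[e$values > 0]),
    trace = sum(diag(R))
  )
  list(
    values = e$values,
    vectors = e$vectors[, seq_len(k), drop = FALSE],
    fraction = e$values[seq_len(k)] / denom
  )
}
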