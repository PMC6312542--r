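# Linkage-disequilibrium decay: pairwise dosage r^2 against physical
# distance, distance-ranked binning, and physical-to-genetic distance
# conversion.

#' Pairwise LD (squared dosage correlation) within chromosomes
#'
#' Computes the squared Pearson correlation of dosage vectors for every pair
#' of loci on the same chromosome (composite LD on unphased genotype
#' counts). Zero-variance loci contribute no pairs and are logged.
#'
#' @param G A complete [genotype_matrix()] whose map carries chromosome and
#'   bp position.
#' @param max_distance Optional maximum pair distance in bp (default
#'   unlimited).
#' @return A list with `pairs` (data.frame: `locus_i`, `locus_j`,
#'   `distance`, `r2`) and `skipped_loci` (zero-variance locus names).
#' @export
ld_pairs <- function(G, max_distance = Inf) {
  stopifnot(inherits(G, "genotype_matrix"), nrow(G$dosages) >= 2L)
  d <- G$dosages
  if (anyNA(d)) stop("LD requires a complete (imputed) matrix")
  v <- apply(d, 2L, stats::var)
  skipped <- colnames(d)[v == 0]
  out <- list()
  for (ch in unique(G$map$chrom)) {
    sel <- which(G$map$chrom == ch & v > 0)
    if (length(sel) < 2L) next
    r <- stats::cor(d[, sel, drop = FALSE])
    pos <- G$map$pos_bp[sel]
    up <- which(upper.tri(r), arr.ind = TRUE)
    dist <- abs(pos[up[, 1L]] - pos[up[, 2L]])
    keep <- dist <= max_distance
    out[[ch]] <- data.frame(
      locus_i = colnames(d)[sel][up[keep, 1L]],
      locus_j = colnames(d)[sel][up[keep, 2L]],
      distance = dist[keep],
      r2 = r[up][keep]^2,
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (length(out)) do.call(rbind, unname(out)) else {
    data.frame(locus_i = character(), locus_j = character(),
               distance = numeric(), r2 = numeric())
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, skipped_loci = skipped)
}

#' Bin LD pairs by distance rank
#'
#' Pairs are sorted by distance and averaged in consecutive groups of
#' `bin_size` (the last bin may be smaller), giving the classic decay curve
#' of mean r^2 against mean distance.
#'
#' @param pairs Pair data.frame from [ld_pairs()] (needs `distance`, `r2`).
#' @param bin_size Pairs per bin.
#' @return Data.frame with `mean_distance`, `mean_r2`, `n_pairs` per bin.
#' @export
bin_ld <- function(pairs, bin_size = 1000) {
  if (is.list(pairs) && !is.data.frame(pairs) && !is.null(pairs$pairs)) {
    pairs <- pairs$pairs
  }
  stopifnot(nrow(pairs) >= 1L, bin_size >= 1)
  ord <- order(pairs$distance)
  grp <- (seq_along(ord) - 1L) %/% bin_size
  data.frame(
    mean_distance = as.numeric(tapply(pairs$distance[ord], grp, mean)),
    mean_r2 = as.numeric(tapply(pairs$r2[ord], grp, mean)),
    n_pairs = as.integer(tapply(pairs$r2[ord], grp, length)),
    row.names = NULL
  )
}

#' Convert physical to genetic distance
#'
#' Uses a constant kilobase-per-centimorgan rate:
#' `cM = (bp / 1000) / kb_per_cM`.
#'
#' @param distance_bp Distance(s) in base pairs.
#' @param kb_per_cM Map rate; default 465 kb per cM.
#' @return Genetic distance(s) in cM.
#' @export
bp_to_cM <- function(distance_bp, kb_per_cM = 465) {
  if (any(kb_per_cM <= 0)) stop("kb_per_cM must be positive")
  if (any(distance_bp < 0)) stop("distances must be non-negative")
  (distance_bp / 1000) / kb_per_cM
}
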