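# SNP-call merging across sources, marker filtering, duplicate DNA-profile
# detection and flanking-marker imputation.

#' Merge genotype calls from several sources
#'
#' Sources are genotype matrices keyed by final individual names and shared
#' locus identifiers. Calls that agree across sources are retained; a call
#' present in exactly one source fills the cell; any disagreement sets the
#' cell to missing and is logged as a conflict. Merging is performed over the
#' union of individuals and loci, and the result does not depend on the
#' order of the sources.
#'
#' @param sets Named list of [genotype_matrix()] objects (names label the
#'   sources in the conflict log).
#' @param map Optional combined locus map for the merged panel; defaults to
#'   the first map entry seen per locus across sources.
#' @return A list with `genotypes` (merged [genotype_matrix()]) and
#'   `conflicts` (data.frame of `id`, `locus` and the conflicting calls
#'   pasted per source).
#' @export
merge_genotype_sources <- function(sets, map = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  sets <- lapply(sets, function(s) {
    if (!inherits(s, "genotype_matrix")) s <- genotype_matrix(s)
    s
  })
  if (is.null(names(sets))) names(sets) <- paste0("source", seq_along(sets))
  loci_list <- lapply(sets, function(s) colnames(s$dosages))
  if (length(sets) > 1L) {
    for (a in seq_len(length(sets) - 1L)) {
      for (b in seq(a + 1L, length(sets))) {
        if (!length(intersect(loci_list[[a]], loci_list[[b]]))) {
          stop("merge error: sources ", sQuote(names(sets)[a]), " and ",
               sQuote(names(sets)[b]), " share no locus identifiers")
        }
      }
    }
  }
  # canonical (sorted) union so the result is order-insensitive
  ids <- sort(unique(unlist(lapply(sets, function(s) rownames(s$dosages)))))
  loci <- sort(unique(unlist(loci_list)))
  n_src <- length(sets)
  agree <- matrix(NA_real_, length(ids), length(loci),
                  dimnames = list(ids, loci))
  conflict <- matrix(FALSE, length(ids), length(loci),
                     dimnames = list(ids, loci))
  for (s in sets) {
    d <- s$dosages
    ri <- match(rownames(d), ids)
    ci <- match(colnames(d), loci)
    cur <- agree[ri, ci, drop = FALSE]
    new <- d
    clash <- !is.na(cur) & !is.na(new) & cur != new
    fill <- is.na(cur) & !is.na(new)
    cur[fill] <- new[fill]
    agree[ri, ci] <- cur
    conflict[ri, ci] <- conflict[ri, ci, drop = FALSE] | clash
  }
  agree[conflict] <- NA_real_
  idx <- which(conflict, arr.ind = TRUE)
  conflicts <- data.frame(
    id = ids[idx[, 1L]], locus = loci[idx[, 2L]],
    stringsAsFactors = FALSE
  )
  conflicts <- conflicts[order(conflicts$id, conflicts$locus), , drop = FALSE]
  rownames(conflicts) <- NULL
  if (is.null(map)) {
    maps <- do.call(rbind, lapply(sets, function(s) s$map))
    map <- maps[!duplicated(maps$locus), , drop = FALSE]
    map <- map[match(loci, map$locus), , drop = FALSE]
  }
  list(genotypes = genotype_matrix(agree, map), conflicts = conflicts)
}

#' Filter SNP loci on missingness and minor allele frequency
#'
#' Removes loci whose missing-call fraction exceeds `max_missing` or whose
#' minor allele frequency, computed on non-missing calls, is below
#' `min_maf`. Retained dosage values and the individual order are unchanged.
#'
#' @param G A [genotype_matrix()].
#' @param max_missing Maximum tolerated fraction of missing calls per locus.
#' @param min_maf Minimum minor allele frequency per locus.
#' @return A list with `genotypes` (filtered panel) and `report`: per-filter
#'   removal counts that reconcile exactly with the input locus count.
#' @export
filter_snps <- function(G, max_missing = 0.30, min_maf = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  n <- nrow(d)
  miss_frac <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_ # all-missing locus: caught by the missing filter
  maf <- pmin(p, 1 - p)
  fail_missing <- miss_frac > max_missing
  fail_maf <- !fail_missing & (is.na(maf) | maf < min_maf)
  keep <- !(fail_missing | fail_maf)
  if (!any(keep)) warning("empty panel: all loci removed by filters")
  report <- list(
    n_loci_in = ncol(d),
    n_removed_missing = sum(fail_missing),
    n_removed_maf = sum(fail_maf),
    n_retained = sum(keep),
    max_missing = max_missing,
    min_maf = min_maf,
    removed = colnames(d)[!keep]
  )
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         G$map[keep, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' Detect duplicate genome-wide DNA profiles
#'
#' Pairs of individuals whose genotype concordance on jointly non-missing
#' loci is at least `concordance` (with at least `min_overlap` such loci)
#' are linked; links are closed transitively so each duplicate group gets
#' one representative (its first member in panel order).
#'
#' @param G A [genotype_matrix()].
#' @param min_overlap Minimum number of jointly called loci for a pair to be
#'   assessable; pairs under this are skipped and logged.
#' @param concordance Concordance threshold for calling a duplicate pair.
#' @return A list with `groups` (list of character vectors, each a duplicate
#'   group of >= 2 individuals), `representatives` (first member of each
#'   group), `keep` (all individuals minus non-representative duplicates)
#'   and `skipped_pairs` (data.frame of pairs with insufficient overlap).
#' @export
find_duplicate_profiles <- function(G, min_overlap = 100, concordance = 0.99) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 individuals")
  ids <- rownames(d)
  obs <- !is.na(d)
  x <- d
  x[!obs] <- 0
  # pairwise counts of jointly called and agreeing loci via matrix products
  overlap <- obs %*% t(obs)
  match0 <- (x == 0 & obs) %*% t(x == 0 & obs)
  match1 <- (x == 1 & obs) %*% t(x == 1 & obs)
  match2 <- (x == 2 & obs) %*% t(x == 2 & obs)
  same <- match0 + match1 + match2
  conc <- same / overlap
  up <- upper.tri(overlap)
  thin <- which(up & overlap < min_overlap, arr.ind = TRUE)
  skipped <- data.frame(
    id1 = ids[thin[, 1L]], id2 = ids[thin[, 2L]],
    overlap = overlap[thin], stringsAsFactors = FALSE
  )
  dup <- up & overlap >= min_overlap & conc >= concordance
  # transitive closure through union-find
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in which(dup)) {
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(n), find, integer(1))
  grp <- split(ids, root)
  groups <- unname(grp[lengths(grp) > 1L])
  reps <- vapply(groups, `[[`, character(1), 1L)
  drop <- setdiff(unlist(groups), reps)
  list(
    groups = groups,
    representatives = reps,
    keep = setdiff(ids, drop),
    skipped_pairs = skipped
  )
}

#' Impute missing genotype calls from flanking markers
#'
#' Single-pass conditional imputation: for each missing cell the nearest
#' non-missing flanking loci (left and right on the same chromosome, in the
#' same individual) are located, and the modal dosage among complete
#' individuals sharing that flanking dosage pair is imputed (ties broken
#' towards the smaller dosage). When no individual matches the flanking
#' pattern — or the locus has no informative flank — the dosage is drawn
#' from the locus Hardy-Weinberg distribution at its observed allele
#' frequency, using the supplied seed. Non-missing entries are never
#' altered and the result is deterministic given the seed.
#'
#' @param G A [genotype_matrix()].
#' @param seed Integer seed for the Hardy-Weinberg fallback draws.
#' @return A list with `genotypes` (complete panel) and `report` (imputed
#'   cell count, fraction, and counts by rule).
#' @export
impute_missing <- function(G, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosages
  miss <- which(is.na(d), arr.ind = TRUE)
  if (nrow(miss) == 0L) {
    return(list(genotypes = G,
                report = list(n_imputed = 0L, fraction = 0,
                              n_flanking = 0L, n_hwe = 0L)))
  }
  all_missing <- colSums(!is.na(d)) == 0L
  if (any(all_missing)) {
    stop("cannot impute locus with all calls missing: ",
         paste(colnames(d)[all_missing][1:5], collapse = ", "))
  }
  p <- colMeans(d, na.rm = TRUE) / 2
  chrom <- G$map$chrom
  pos <- G$map$pos_bp
  ord <- order(chrom, pos)           # loci in map order within chromosome
  col_rank <- match(seq_len(ncol(d)), ord)
  out <- d
  n_flank <- 0L
  n_hwe <- 0L
  hwe_draws <- with_seed(derive_seed(seed, "impute"), {
    stats::runif(nrow(miss))
  })
  for (k in seq_len(nrow(miss))) {
    i <- miss[k, 1L]
    j <- miss[k, 2L]
    rj <- col_rank[j]
    # scan outwards for nearest called flanking loci on the same chromosome
    left <- NA_integer_
    r <- rj - 1L
    while (r >= 1L) {
      jj <- ord[r]
      if (chrom[jj] != chrom[j]) break
      if (!is.na(d[i, jj])) { left <- jj; break }
      r <- r - 1L
    }
    right <- NA_integer_
    r <- rj + 1L
    while (r <= ncol(d)) {
      jj <- ord[r]
      if (chrom[jj] != chrom[j]) break
      if (!is.na(d[i, jj])) { right <- jj; break }
      r <- r + 1L
    }
    val <- NA_real_
    if (!is.na(left) || !is.na(right)) {
      ok <- !is.na(d[, j])
      if (!is.na(left)) ok <- ok & !is.na(d[, left]) & d[, left] == d[i, left]
      if (!is.na(right)) ok <- ok & !is.na(d[, right]) & d[, right] == d[i, right]
      ok[i] <- FALSE
      if (any(ok)) {
        tab <- tabulate(d[ok, j] + 1, nbins = 3L)
        val <- which.max(tab) - 1 # which.max takes the first (smallest) mode
        n_flank <- n_flank + 1L
      }
    }
    if (is.na(val)) {
      pj <- p[j]
      cum <- cumsum(c((1 - pj)^2, 2 * pj * (1 - pj), pj^2))
      val <- findInterval(hwe_draws[k], cum) # 0, 1, 2
      n_hwe <- n_hwe + 1L
    }
    out[i, j] <- val
  }
  list(
    genotypes = genotype_matrix(out, G$map),
    report = list(
      n_imputed = nrow(miss),
      fraction = nrow(miss) / length(d),
      n_flanking = n_flank,
      n_hwe = n_hwe
    )
  )
}

#' Summarize a curation run
#'
#' Collects the per-stage reports of a curation pipeline into one record
#' (counts removed per filter, conflicts, duplicate groups, imputed cells).
#'
#' @param filter_report Report from [filter_snps()].
#' @param conflicts Conflict log from [merge_genotype_sources()].
#' @param duplicates Result of [find_duplicate_profiles()].
#' @param impute_report Report from [impute_missing()].
#' @return A list of class `curation_report`.
#' @export
curation_report <- function(filter_report = NULL, conflicts = NULL,
                            duplicates = NULL, impute_report = NULL) {
  structure(
    list(
      filters = filter_report,
      n_conflicts = if (is.null(conflicts)) NA_integer_ else nrow(conflicts),
      n_duplicate_groups = if (is.null(duplicates)) {
        NA_integer_
      } else {
        length(duplicates$groups)
      },
      n_duplicates_dropped = if (is.null(duplicates)) {
        NA_integer_
      } else {
        length(unlist(duplicates$groups)) - length(duplicates$groups)
      },
      imputation = impute_report
    ),
    class = "curation_report"
  )
}
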