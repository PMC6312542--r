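# Pedigree numerator relationship matrix (tabular method).

#' Topologically sort and validate a pedigree
#'
#' @param ped Data.frame with columns `id`, `parent1`, `parent2`; unknown
#'   parents are `NA` or `""`. Parents referenced but not listed as
#'   individuals are added as founders.
#' @return The pedigree data.frame, parents before offspring, with empty
#'   parent codes normalized to `NA`.
#' @export
sort_pedigree <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "parent1", "parent2") %in% names(ped)))
  for (col in c("id", "parent1", "parent2")) {
    ped[[col]] <- as.character(ped[[col]])
    ped[[col]][!is.na(ped[[col]]) & ped[[col]] == ""] <- NA_character_
  }
  if (anyDuplicated(ped$id)) stop("duplicate individuals in pedigree")
  parents <- setdiff(stats::na.omit(c(ped$parent1, ped$parent2)), ped$id)
  if (length(parents)) {
    ped <- rbind(
      data.frame(id = parents, parent1 = NA_character_,
                 parent2 = NA_character_, stringsAsFactors = FALSE),
      ped[, c("id", "parent1", "parent2")]
    )
  }
  # Kahn's algorithm; leftover nodes mean a cycle
  placed <- character(0)
  remaining <- ped
  sorted <- ped[0, ]
  while (nrow(remaining)) {
    ready <- (is.na(remaining$parent1) | remaining$parent1 %in% placed) &
      (is.na(remaining$parent2) | remaining$parent2 %in% placed)
    if (!any(ready)) {
      stop("pedigree cycle involving: ",
           paste(remaining$id, collapse = ", "))
    }
    sorted <- rbind(sorted, remaining[ready, , drop = FALSE])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  rownames(sorted) <- NULL
  sorted
}

#' Pedigree-derived additive relationship matrix
#'
#' Numerator relationship matrix by the tabular method: founders have
#' diagonal 1 (non-inbred, unrelated), an offspring's relationship with any
#' earlier individual is the mean of its parents' relationships with that
#' individual, and its diagonal is `1 + F` with inbreeding `F` equal to half
#' the parents' relationship.
#'
#' @param ped Pedigree data.frame (see [sort_pedigree()]); cycles are
#'   rejected with the offending loop named.
#' @return A `relationship_matrix` of kind `"pedigree"` over all pedigree
#'   members.
#' @export
pedigree_A <- function(ped) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  p1 <- match(ped$parent1, ids)
  p2 <- match(ped$parent2, ids)
  for (i in seq_len(n)) {
    s <- p1[i]
    d <- p2[i]
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        a <- if (!is.na(s)) A[j, s] else 0
        b <- if (!is.na(d)) A[j, d] else 0
        A[j, i] <- A[i, j] <- 0.5 * (a + b)
      }
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  relationship_matrix(A, kind = "pedigree")
}

#' Read a 3-column pedigree CSV
#'
#' Columns: individual, parent1, parent2; empty cells denote unknown
#' parents.
#'
#' @param file CSV path.
#' @return Pedigree data.frame with columns `id`, `parent1`, `parent2`.
#' @export
read_pedigree_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = "character")
  names(d)[1:3] <- c("id", "parent1", "parent2")
  d
}
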