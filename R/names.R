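# Germplasm name standardization and dictionary matching.
#
# Multi-source trials record the same cultivar under many spellings
# ("0900 Ziraat", "0900-ziraat", "Precoce d'Isigny"...). All curation keys
# individuals by a canonical lowercase token so that genotype and phenotype
# records from different programs can be linked.

# minimal Latin diacritic fold (both cases, \u escapes keep the source
# ASCII); anything still non-ASCII afterwards is treated as a special
# character and deleted
.diacritic_from <- paste0(
  "\u00e0\u00e1\u00e2\u00e3\u00e4\u00e5\u00e7\u00e8\u00e9\u00ea\u00eb\u00ec\u00ed\u00ee\u00ef\u00f1\u00f2\u00f3\u00f4\u00f5\u00f6\u00f9\u00fa\u00fb\u00fc\u00fd\u00ff\u0153\u00e6\u0161\u017e\u0107\u010d\u0142\u00f8",
  "\u00c0\u00c1\u00c2\u00c3\u00c4\u00c5\u00c7\u00c8\u00c9\u00ca\u00cb\u00cc\u00cd\u00ce\u00cf\u00d1\u00d2\u00d3\u00d4\u00d5\u00d6\u00d9\u00da\u00db\u00dc\u00dd\u0178\u0152\u00c6\u0160\u017d\u0106\u010c\u0141\u00d8"
)
.diacritic_to <- paste0(
  "aaaaaaceeeeiiiinooooouuuuyyoaszcclo",
  "aaaaaaceeeeiiiinooooouuuuyyoaszcclo"
)

#' Standardize a germplasm name to a canonical token
#'
#' Applies the curation rules used to link individuals across data sources:
#' diacritics are folded to their ASCII base letter, upper case is lowered,
#' runs of whitespace (and whitespace-like separators) become a single
#' underscore, and any remaining special character (apostrophes, punctuation,
#' unknown symbols) is deleted without inserting a separator. The mapping is
#' deterministic and idempotent.
#'
#' @param original Character vector of free-text names.
#' @return Character vector of canonical tokens matching `^[a-z0-9_]+$`.
#' @examples
#' format_name("Bing")              # "bing"
#' format_name("0900 Ziraat")       # "0900_ziraat"
#' format_name("Precoce d'Isigny")  # "precoce_disigny"
#' @export
format_name <- function(original) {
  if (length(original) == 0L) stop("no names supplied")
  if (any(is.na(original)) || any(!nzchar(trimws(original)))) {
    stop("invalid name: empty input")
  }
  x <- trimws(as.character(original))
  x <- chartr(.diacritic_from, .diacritic_to, x)
  x <- tolower(x)
  x <- gsub("[[:space:]]+", "_", x)
  x <- gsub("[^a-z0-9_]", "", x)
  x <- gsub("_+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  if (any(!nzchar(x))) {
    bad <- original[!nzchar(x)]
    stop("invalid name: no alphanumeric content in ", paste(sQuote(bad), collapse = ", "))
  }
  x
}

#' Create a name dictionary
#'
#' A dictionary maps formatted names to final linkage keys. Final names are
#' the formatted names used to join data when the same individual appears in
#' several sources.
#'
#' @param original Character vector of original free-text names.
#' @param final Optional character vector of final linkage keys (already
#'   formatted); defaults to the formatted original.
#' @return A data.frame of class `name_dictionary` with columns
#'   `original`, `formatted`, `final`.
#' @export
name_dictionary <- function(original = character(), final = NULL) {
  formatted <- if (length(original)) format_name(original) else character()
  if (is.null(final)) final <- formatted
  stopifnot(length(final) == length(formatted))
  d <- data.frame(
    original = as.character(original),
    formatted = formatted,
    final = as.character(final),
    stringsAsFactors = FALSE
  )
  class(d) <- c("name_dictionary", "data.frame")
  d
}

#' Match a formatted name against a dictionary
#'
#' Exact matches return the linked final name. Otherwise partial candidates
#' are proposed: dictionary entries for which one token is a substring of the
#' other, or whose normalized Levenshtein distance (edit distance divided by
#' the longer length) is at most `max_dist`. Candidates are ranked by
#' normalized distance, ties broken alphabetically. No match is a valid
#' outcome and signals that the token should be appended to the dictionary.
#'
#' @param formatted A single canonical token (see [format_name()]).
#' @param dictionary A [name_dictionary()].
#' @param max_dist Maximum normalized edit distance for a partial candidate.
#' @return A list with `status` (`"exact"`, `"partial"` or `"none"`),
#'   `final` (linkage key for an exact match, else `NA`), and `candidates`
#'   (data.frame of `formatted`, `final`, `distance`, ranked).
#' @export
match_names <- function(formatted, dictionary, max_dist = 0.2) {
  stopifnot(length(formatted) == 1L, inherits(dictionary, "name_dictionary"))
  empty <- data.frame(
    formatted = character(), final = character(),
    distance = numeric(), stringsAsFactors = FALSE
  )
  hit <- which(dictionary$formatted == formatted)
  if (length(hit)) {
    return(list(
      status = "exact", final = dictionary$final[hit[1L]],
      candidates = empty
    ))
  }
  if (nrow(dictionary) == 0L) {
    return(list(status = "none", final = NA_character_, candidates = empty))
  }
  cand <- unique(dictionary[, c("formatted", "final")])
  dist <- as.numeric(utils::adist(formatted, cand$formatted)) /
    pmax(nchar(formatted), nchar(cand$formatted))
  substr_hit <- mapply(
    function(a, b) grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE),
    formatted, cand$formatted
  )
  keep <- substr_hit | dist <= max_dist
  if (!any(keep)) {
    return(list(status = "none", final = NA_character_, candidates = empty))
  }
  out <- as.data.frame(cand[keep, , drop = FALSE])
  class(out) <- "data.frame"
  out$distance <- dist[keep]
  out <- out[order(out$distance, out$formatted), , drop = FALSE]
  rownames(out) <- NULL
  list(status = "partial", final = NA_character_, candidates = out)
}
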