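# Standardized long-format phenotype tables.
#
# All sources are reshaped to one record per observation unit using a fixed
# vocabulary of design fields, so that trials run by different programs can
# be combined into one analysis.

#' Standard phenotype field vocabulary
#'
#' The field names every standardized phenotype table carries, in order.
#' `REF_ID` is the standardized genetic treatment (final germplasm name),
#' `Experimental.unit` the smallest unit receiving a unique genetic
#' treatment, `Observation.unit` the experimental unit crossed with the
#' repeat factor (year), and `y` the untransformed observation.
#'
#' @return Character vector of standard field names.
#' @export
phenotype_fields <- function() {
  c(
    "Location", "Trial", "Section", "Row", "Position", "Block", "Plot",
    "Plant", "Planting.date", "REF_ID", "Experimental.unit", "Year",
    "Observation.unit", "y"
  )
}

#' Standardize source phenotype records into the long-format schema
#'
#' Renames source fields to the standard vocabulary, reshapes wide
#' season/year columns to long format when requested, synthesizes
#' `Experimental.unit` (combination of the design units and the genetic
#' treatment) and `Observation.unit` (experimental unit x year), and keeps
#' unmapped source columns verbatim. `REF_ID` values are passed through
#' [format_name()] and resolved against an optional dictionary.
#'
#' @param records Source data.frame.
#' @param field_map Named character vector mapping standard field names to
#'   source column names; must cover at least `REF_ID`, `Location`, `Year`
#'   and `y`. For wide tables, map `Year` to `NA` and supply `year_columns`.
#' @param year_columns Optional named character vector: names are year
#'   labels, values are the source columns holding that year's observation
#'   (wide-to-long reshape).
#' @param dictionary Optional [name_dictionary()] used to resolve formatted
#'   `REF_ID`s to final names (exact matches only; unmatched tokens are kept
#'   as their formatted form).
#' @return A data.frame of class `phenotype_table` with the columns of
#'   [phenotype_fields()] followed by any unmapped source columns. Fails if
#'   two records share the same (`Experimental.unit`, `Year`).
#' @export
standardize_phenotypes <- function(records, field_map, year_columns = NULL,
                                   dictionary = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  field_map <- unlist(field_map)
  mandatory <- c("REF_ID", "Location")
  if (is.null(year_columns)) mandatory <- c(mandatory, "Year", "y")
  missing_map <- setdiff(mandatory, names(field_map))
  if (length(missing_map)) {
    stop("schema error: field_map lacks mandatory field(s): ",
         paste(missing_map, collapse = ", "))
  }
  bad_src <- setdiff(stats::na.omit(unname(field_map)), names(records))
  if (length(bad_src)) {
    stop("schema error: source columns not found: ",
         paste(bad_src, collapse = ", "))
  }
  if (!is.null(year_columns)) {
    # wide-to-long: one record per (row, year column)
    stopifnot(!is.null(names(year_columns)))
    long <- do.call(rbind, lapply(names(year_columns), function(yr) {
      d <- records
      d$.Year <- yr
      d$.y <- records[[year_columns[[yr]]]]
      d[, setdiff(names(d), unname(year_columns)), drop = FALSE]
    }))
    records <- long
    field_map <- field_map[setdiff(names(field_map), c("Year", "y"))]
    field_map <- c(field_map, Year = ".Year", y = ".y")
  }
  out <- data.frame(row.names = seq_len(nrow(records)))
  for (f in phenotype_fields()) {
    src <- unname(field_map[f])
    out[[f]] <- if (!is.na(src)) records[[src]] else NA
  }
  out$y <- as.numeric(out$y)
  ref <- format_name(as.character(out$REF_ID))
  if (!is.null(dictionary)) {
    ref <- vapply(ref, function(r) {
      m <- match_names(r, dictionary)
      if (m$status == "exact") m$final else r
    }, character(1), USE.NAMES = FALSE)
  }
  out$REF_ID <- ref
  design <- c("Location", "Trial", "Section", "Block", "Plot", "Plant")
  if (all(is.na(out$Experimental.unit))) {
    parts <- lapply(design, function(f) {
      v <- out[[f]]
      if (all(is.na(v))) NULL else as.character(v)
    })
    parts <- c(Filter(Negate(is.null), parts), list(out$REF_ID))
    out$Experimental.unit <- do.call(paste, c(parts, sep = ":"))
  }
  if (all(is.na(out$Observation.unit))) {
    out$Observation.unit <- paste(out$Experimental.unit, out$Year, sep = ":")
  }
  extra <- setdiff(names(records),
                   c(unname(stats::na.omit(field_map)), ".Year", ".y"))
  for (e in extra) out[[e]] <- records[[e]]
  dup <- duplicated(out[, c("Experimental.unit", "Year")])
  if (any(dup)) {
    stop("duplicate observation: experimental unit ",
         sQuote(out$Experimental.unit[dup][1L]), " measured twice in year ",
         out$Year[dup][1L])
  }
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read / write standardized phenotype tables
#'
#' CSV round-trip using the standard header vocabulary; unknown columns are
#' passed through.
#'
#' @param file Path to the CSV file.
#' @return `read_phenotype_csv` returns a `phenotype_table`.
#' @export
read_phenotype_csv <- function(file) {
  d <- utils::read.csv(file, check.names = TRUE, stringsAsFactors = FALSE)
  need <- c("Location", "REF_ID", "Year", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("phenotype CSV lacks required column(s): ", paste(miss, collapse = ", "))
  }
  for (f in setdiff(phenotype_fields(), names(d))) d[[f]] <- NA
  d <- d[, c(phenotype_fields(), setdiff(names(d), phenotype_fields())),
         drop = FALSE]
  d$y <- as.numeric(d$y)
  class(d) <- c("phenotype_table", "data.frame")
  d
}

#' @rdname read_phenotype_csv
#' @param pheno A `phenotype_table`.
#' @export
write_phenotype_csv <- function(pheno, file) {
  utils::write.csv(as.data.frame(pheno), file, row.names = FALSE)
  invisible(file)
}
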