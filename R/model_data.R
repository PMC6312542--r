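# Assembly of phenotype records into model-ready form: environment keys,
# fixed-effect design, random-effect index maps and residual structure.

#' Assemble model data from a phenotype table and relationship matrix
#'
#' Builds the observation vector and factor indexes used by the REML fitter:
#' each record carries its individual (must appear in `G_A`), its
#' location-by-season environment key, its experimental unit, and optionally
#' a planting-year level used as an extra fixed effect at one designated
#' location. Records with missing `y` are excluded from fitting.
#'
#' @param pheno A `phenotype_table` (needs `REF_ID`, `Location`, `Year`,
#'   `y`; `Experimental.unit` recommended; `Planting.date` used when
#'   `planting_year_location` is set).
#' @param G_A A `relationship_matrix` over individuals.
#' @param planting_year_location Optional location label at which the
#'   planting-year fixed effect applies (the only location where that
#'   factor is relevant).
#' @return A list of class `model_data`: `y`, `env` (factor
#'   `location:season`), `location`, `season`, `id`, `unit`, `py`
#'   (planting-year factor or `NA`), `envs` (environment levels,
#'   location-major), `n_dropped_missing_y`.
#' @export
model_data <- function(pheno, G_A, planting_year_location = NULL) {
  d <- as.data.frame(pheno)
  need <- c("REF_ID", "Location", "Year", "y")
  stopifnot(all(need %in% names(d)))
  keep <- !is.na(d$y)
  n_dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]
  if (!nrow(d)) stop("no records with non-missing y")
  unknown <- setdiff(unique(d$REF_ID), rownames(G_A))
  if (length(unknown)) {
    stop("individuals absent from relationship matrix: ",
         paste(unknown[1:min(5, length(unknown))], collapse = ", "))
  }
  loc <- as.character(d$Location)
  season <- as.character(d$Year)
  env <- paste(loc, season, sep = ":")
  env_levels <- unique(env[order(loc, season)])
  unit <- if ("Experimental.unit" %in% names(d) &&
              !all(is.na(d$Experimental.unit))) {
    as.character(d$Experimental.unit)
  } else {
    paste(loc, d$REF_ID, sep = ":")
  }
  py <- rep(NA_character_, nrow(d))
  if (!is.null(planting_year_location)) {
    at <- loc == planting_year_location
    if (!"Planting.date" %in% names(d) || all(is.na(d$Planting.date[at]))) {
      stop("planting_year_location set but Planting.date is empty there")
    }
    py[at] <- as.character(d$Planting.date[at])
  }
  structure(
    list(
      y = as.numeric(d$y),
      env = factor(env, levels = env_levels),
      location = factor(loc, levels = unique(loc[order(loc)])),
      season = season,
      id = as.character(d$REF_ID),
      unit = unit,
      py = py,
      envs = env_levels,
      planting_year_location = planting_year_location,
      n_dropped_missing_y = n_dropped
    ),
    class = "model_data"
  )
}

#' @export
print.model_data <- function(x, ...) {
  cat("model_data:", length(x$y), "records,",
      length(unique(x$id)), "individuals,",
      length(x$envs), "environments\n")
  invisible(x)
}

#' Fixed-effect design matrix and random-effect index maps
#'
#' Builds `X` with an intercept, treatment-coded environment effects (first
#' environment as reference) and, where a planting-year location is
#' configured, treatment-coded planting-year effects for records at that
#' location only. Also returns the index maps realizing `Z`: each record's
#' environment index and individual index into the `n_G x n_E` vector of
#' breeding values (individual-major within environment).
#'
#' @param data A [model_data()].
#' @param ids Individual labels ordering the breeding-value vector
#'   (typically `rownames(G_A)`).
#' @return A list with `X`, `env_index`, `id_index`, `envs`, `ids`,
#'   `py_levels`. Environments with zero records are dropped with a
#'   warning. `X` is checked to be full column rank.
#' @export
build_design <- function(data, ids = NULL) {
  stopifnot(inherits(data, "model_data"))
  empty <- setdiff(levels(data$env), unique(as.character(data$env)))
  if (length(empty)) {
    warning("dropping environment(s) with no records: ",
            paste(empty, collapse = ", "))
    data$env <- droplevels(data$env)
    data$envs <- levels(data$env)
  }
  X <- if (nlevels(data$env) > 1L) {
    stats::model.matrix(~env, data = data.frame(env = data$env))
  } else {
    matrix(1, length(data$y), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  py_levels <- NULL
  if (any(!is.na(data$py))) {
    py_levels <- sort(unique(stats::na.omit(data$py)))
    if (length(py_levels) > 1L) {
      for (lv in py_levels[-1L]) {
        X <- cbind(X, as.numeric(!is.na(data$py) & data$py == lv))
        colnames(X)[ncol(X)] <- paste0("py", lv)
      }
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("fixed-effect design is rank deficient (confounded levels)")
  }
  if (is.null(ids)) ids <- sort(unique(data$id))
  id_index <- match(data$id, ids)
  if (anyNA(id_index)) stop("record individual missing from ids")
  list(
    X = X,
    env_index = as.integer(data$env),
    id_index = id_index,
    envs = levels(data$env),
    ids = ids,
    py_levels = py_levels
  )
}

#' Residual covariance matrix from per-location season blocks
#'
#' Builds the dense `N x N` residual covariance: records from the same
#' experimental unit at the same location get the covariance of their
#' seasons from that location's `R_Sj` block; records from distinct units
#' are independent.
#'
#' @param rs Named list (per location) of season covariance matrices with
#'   season labels as dimnames.
#' @param data A [model_data()].
#' @return Dense residual covariance matrix.
#' @export
residual_cov <- function(rs, data) {
  stopifnot(inherits(data, "model_data"))
  N <- length(data$y)
  R <- matrix(0, N, N)
  loc <- as.character(data$location)
  for (r in seq_len(N)) {
    Rj <- rs[[loc[r]]]
    if (is.null(Rj)) stop("no residual block for location ", loc[r])
    sr <- as.character(data$season[r])
    if (!sr %in% rownames(Rj)) {
      stop("season ", sr, " missing from residual block of ", loc[r])
    }
    R[r, r] <- Rj[sr, sr]
  }
  # off-diagonals: same unit, same location, different records
  for (u in unique(data$unit[duplicated(data$unit)])) {
    recs <- which(data$unit == u)
    for (a in recs) {
      for (b in recs) {
        if (a >= b) next
        if (loc[a] != loc[b]) next
        Rj <- rs[[loc[a]]]
        R[a, b] <- R[b, a] <- Rj[as.character(data$season[a]),
                                 as.character(data$season[b])]
      }
    }
  }
  R
}
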