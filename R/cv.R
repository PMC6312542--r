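# Cross-validation schemes for genomic prediction accuracy.
#
# Both schemes refit the factor-analytic G x E model with the validation
# records removed, predict breeding values for the masked cells, and
# correlate predictions with adjusted phenotypes from the full-data fit.
# Heritabilities for converting predictive ability (PA) into prediction
# accuracy (PACC) always come from the full-data fit.

cv_config <- function(scheme = c("within_location_kfold", "leave_location_out"),
                      k = 5, seed = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "within_location_kfold" && k < 2) stop("k must be >= 2")
  list(scheme = scheme, k = k, seed = as.integer(seed))
}

# subset a model_data by record index
subset_model_data <- function(data, keep) {
  d <- data
  d$y <- data$y[keep]
  d$env <- droplevels(data$env[keep])
  d$location <- droplevels(data$location[keep])
  d$season <- data$season[keep]
  d$id <- data$id[keep]
  d$unit <- data$unit[keep]
  d$py <- data$py[keep]
  d$envs <- levels(d$env)
  d
}

# mean adjusted phenotype per (id, env); multiple observation units on the
# same individual-environment cell are averaged before correlating
mean_y_adj <- function(adj) {
  agg <- stats::aggregate(y_adj ~ id + env, data = adj, FUN = mean)
  agg
}

# refit on training records, warm-started from the full fit
cv_refit <- function(data, G_A, full_fit, keep, max_iter = 100) {
  train <- subset_model_data(data, keep)
  start <- NULL
  if (identical(train$envs, full_fit$envs)) start <- full_fit$theta
  fit <- tryCatch(
    fit_reml(train, G_A, kind = full_fit$kind, start = start,
             max_iter = max_iter, bend = full_fit$bend),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    # fall back to the full-data parameters rather than dropping the fold
    warning("training fold did not converge; using full-data parameters")
    if (is.null(fit) || identical(train$envs, full_fit$envs)) {
      fit <- full_fit
    }
  }
  list(train = train, fit = fit)
}

#' Within-location k-fold cross-validation
#'
#' Individuals at each location are randomly assigned to `k` sets
#' (stratified by location only). For each location-by-set validation
#' population, the records of those individuals at that location are
#' masked, the factor-analytic model is refit on the training records
#' (warm-started from the full fit), and their breeding values at that
#' location's environments are predicted. PA is the correlation between
#' predictions and the full-fit adjusted phenotypes, computed per
#' location-by-set-by-season and then averaged over sets to the season
#' level. `PACC = PA / sqrt(h2)` uses the full-data heritability of the
#' environment, and `se.PACC = 1 / sqrt(n)` uses the mean season-level
#' validation count.
#'
#' @param data A [model_data()].
#' @param G_A Genomic relationship matrix.
#' @param full_fit A converged full-data `gxe_fit` (kind `fa1` in the
#'   standard pipeline; any kind works).
#' @param k Number of folds.
#' @param seed Integer seed for fold assignment.
#' @param min_n Folds with fewer validation phenotypes in a season are
#'   flagged (`PA = NA`).
#' @param max_iter Iteration cap for the training refits.
#' @return A list of class `cv_result`: `results` (per location-by-season:
#'   `location`, `season`, `n_GxL`, `n_GxLS`, `PA`, `PACC`, `se.PACC`),
#'   `folds` (per location-by-set-by-season PA), `scheme`, `seed`.
#' @export
within_location_cv <- function(data, G_A, full_fit, k = 5, seed = 1,
                               min_n = 3, max_iter = 100) {
  adj <- adjust_phenotypes(data, full_fit, G_A)
  adj_cell <- mean_y_adj(adj)
  h2 <- heritability_table(full_fit)
  loc_all <- as.character(data$location)
  fold_rows <- list()
  assign_seed <- derive_seed(seed, "cv_folds")
  fold_of <- list() # location -> named fold vector
  with_seed(assign_seed, {
    for (l in unique(loc_all)) {
      ids_l <- unique(data$id[loc_all == l])
      f <- sample(rep_len(seq_len(k), length(ids_l)))
      fold_of[[l]] <- stats::setNames(f, ids_l)
    }
  })
  for (l in unique(loc_all)) {
    for (s in seq_len(k)) {
      val_ids <- names(fold_of[[l]])[fold_of[[l]] == s]
      mask <- loc_all == l & data$id %in% val_ids
      if (!any(mask)) next
      rf <- cv_refit(data, G_A, full_fit, keep = !mask, max_iter = max_iter)
      pred <- solve_mme(subset_model_data(data, !mask), G_A, rf$fit,
                        pev = FALSE)
      for (env in unique(as.character(data$env[mask]))) {
        season <- sub("^.*:", "", env)
        cells <- adj_cell[adj_cell$env == env & adj_cell$id %in% val_ids, ]
        n_v <- nrow(cells)
        pa <- if (n_v >= min_n) {
          stats::cor(pred$blup[cells$id, env], cells$y_adj)
        } else {
          NA_real_
        }
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          location = l, season = season, set = s, env = env,
          n = n_v, PA = pa, flagged = n_v < min_n,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  folds <- do.call(rbind, fold_rows)
  results <- do.call(rbind, lapply(
    split(folds, list(folds$location, folds$season), drop = TRUE),
    function(d) {
      env <- d$env[1L]
      h2_env <- h2$h2[h2$env == env]
      pa <- mean(d$PA, na.rm = TRUE)
      n_ls <- mean(d$n)
      data.frame(
        location = d$location[1L], season = d$season[1L],
        n_GxL = length(unique(data$id[loc_all == d$location[1L]])) / k,
        n_GxLS = n_ls,
        PA = pa,
        PACC = prediction_accuracy(pa, h2_env),
        se.PACC = se_pacc(n_ls),
        stringsAsFactors = FALSE
      )
    }
  ))
  rownames(results) <- NULL
  structure(
    list(results = results, folds = folds,
         scheme = "within_location_kfold", k = k, seed = seed),
    class = "cv_result"
  )
}

#' Leave-one-location-out cross-validation
#'
#' For each location, all of its records are dropped, the model is refit on
#' the remaining locations, and each dropped individual's breeding values
#' in the preserved environments are averaged into a single prediction. PA
#' correlates that mean prediction with the dropped location's adjusted
#' phenotypes, per season; PACC uses the dropped environments' full-data
#' heritabilities.
#'
#' @inheritParams within_location_cv
#' @return A `cv_result` (see [within_location_cv()]); `n_GxL` is the
#'   number of individuals at the dropped location.
#' @export
leave_location_out_cv <- function(data, G_A, full_fit, min_n = 3,
                                  max_iter = 100) {
  if (length(unique(as.character(data$location))) < 2L) {
    stop("leave-location-out needs at least 2 locations")
  }
  adj <- adjust_phenotypes(data, full_fit, G_A)
  adj_cell <- mean_y_adj(adj)
  h2 <- heritability_table(full_fit)
  loc_all <- as.character(data$location)
  rows <- list()
  for (l in unique(loc_all)) {
    mask <- loc_all == l
    drop_ids <- unique(data$id[mask])
    rf <- cv_refit(data, G_A, full_fit, keep = !mask,
                   max_iter = max_iter)
    pred <- solve_mme(rf$train, G_A, rf$fit, pev = FALSE)
    preserved <- setdiff(full_fit$envs, unique(as.character(data$env[mask])))
    preserved <- intersect(preserved, colnames(pred$blup))
    u_mean <- rowMeans(pred$blup[drop_ids, preserved, drop = FALSE])
    for (env in unique(as.character(data$env[mask]))) {
      season <- sub("^.*:", "", env)
      cells <- adj_cell[adj_cell$env == env & adj_cell$id %in% drop_ids, ]
      n_v <- nrow(cells)
      pa <- if (n_v >= min_n) {
        stats::cor(u_mean[cells$id], cells$y_adj)
      } else {
        NA_real_
      }
      h2_env <- h2$h2[h2$env == env]
      rows[[length(rows) + 1L]] <- data.frame(
        location = l, season = season,
        n_GxL = length(drop_ids), n_GxLS = n_v,
        PA = pa,
        PACC = prediction_accuracy(pa, h2_env),
        se.PACC = se_pacc(max(n_v, 1)),
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(
    list(results = results, folds = NULL,
         scheme = "leave_location_out", seed = NA_integer_),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result [", x$scheme, "]\n")
  print(x$results, digits = 3)
  invisible(x)
}
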