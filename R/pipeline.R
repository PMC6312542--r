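# End-to-end orchestration: curation -> relatedness -> model fits ->
# evaluation, with every seed and threshold logged in the result bundle.

#' Run the full multi-environment genomic prediction analysis
#'
#' Executes the standard sequence on curated inputs: genomic relationship
#' matrix, LD decay and eigen-ordination; uniform, compound-symmetry and
#' factor-analytic REML fits (each warm-starting the next); likelihood
#' ratio tests; heritability, average genetic correlation and
#' environment-mean tables; full-data BLUPs; and, optionally, both
#' cross-validation schemes.
#'
#' @param geno A complete (imputed) [genotype_matrix()].
#' @param pheno A `phenotype_table`.
#' @param pedigree Optional pedigree data.frame for a pedigree relationship
#'   comparison.
#' @param structures Structure kinds to fit, in nesting order.
#' @param planting_year_location Passed to [model_data()].
#' @param cv Run the two cross-validation schemes? (`"none"`, `"within"`,
#'   `"across"` or `"both"`.)
#' @param k Folds for within-location CV.
#' @param seed Seed for fold assignment.
#' @param ld_bin_size Pairs per LD bin.
#' @param kb_per_cM Map rate for the LD distance conversion.
#' @param max_iter REML iteration cap.
#' @param out_dir Optional directory: writes the bundle as CSV/JSON files.
#' @return A list of class `gxe_analysis` with elements `grm`, `ld_bins`,
#'   `ordination`, `fits` (per structure), `lrt` (pairwise tests), `h2`
#'   (heritability table of the most complex fit), `avg_correlation` (from
#'   the cs fit), `env_correlations` (implied, most complex fit),
#'   `lsmeans`, `blup`, `cv_within`, `cv_across`, `pedigree_A`, `settings`.
#' @export
run_full_analysis <- function(geno, pheno, pedigree = NULL,
                              structures = c("uniform", "cs", "fa1"),
                              planting_year_location = NULL,
                              cv = c("both", "within", "across", "none"),
                              k = 5, seed = 1, ld_bin_size = 1000,
                              kb_per_cM = 465, max_iter = 200,
                              out_dir = NULL) {
  cv <- match.arg(cv)
  stage <- "relatedness"
  res <- list(settings = list(structures = structures, k = k, seed = seed,
                              ld_bin_size = ld_bin_size,
                              kb_per_cM = kb_per_cM, max_iter = max_iter))
  tryCatch({
    p <- allele_frequencies(geno)
    res$grm <- vanraden_grm(geno, p)
    ld <- ld_pairs(geno)
    res$ld_bins <- bin_ld(ld$pairs, bin_size = ld_bin_size)
    res$ld_bins$mean_cM <- bp_to_cM(res$ld_bins$mean_distance, kb_per_cM)
    assignments <- unique(data.frame(
      id = as.character(pheno$REF_ID),
      location = as.character(pheno$Location),
      stringsAsFactors = FALSE
    ))
    C <- individual_by_location_grm(res$grm, assignments)
    res$ordination <- eigen_ordination(C, k = 2)
    if (!is.null(pedigree)) res$pedigree_A <- pedigree_A(pedigree)

    stage <- "model fitting"
    data <- model_data(pheno, res$grm,
                       planting_year_location = planting_year_location)
    res$data <- data
    fits <- list()
    start <- NULL
    for (s in structures) {
      fits[[s]] <- fit_reml(data, res$grm, kind = s,
                            start = warm_start(s, fits, data),
                            max_iter = max_iter)
    }
    res$fits <- fits
    stage <- "model comparison"
    nE <- length(data$envs)
    res$lrt <- list()
    for (i in seq_along(structures)[-1L]) {
      a <- structures[i - 1L]
      b <- structures[i]
      res$lrt[[paste(b, "vs", a)]] <-
        lrt(fits[[a]], fits[[b]], structure_df(a, b, nE))
    }
    best <- structures[length(structures)]
    stage <- "evaluation"
    res$h2 <- heritability_table(fits[[best]])
    if ("cs" %in% structures) {
      res$avg_correlation <- avg_env_correlation(
        fits$cs$structure$sigma2_A, fits$cs$structure$sigma2_AxE
      )
    }
    res$env_correlations <- implied_env_correlations(
      fits[[best]]$structure, nE
    )
    res$lsmeans <- lsmeans_envs(fits[[best]])
    res$blup <- solve_mme(data, res$grm, fits[[best]])
    if (cv %in% c("both", "within")) {
      stage <- "within-location cross-validation"
      res$cv_within <- within_location_cv(data, res$grm, fits[[best]],
                                          k = k, seed = seed,
                                          max_iter = max_iter)
    }
    if (cv %in% c("both", "across")) {
      stage <- "leave-location-out cross-validation"
      res$cv_across <- leave_location_out_cv(data, res$grm, fits[[best]],
                                             max_iter = max_iter)
    }
  }, error = function(e) {
    stop("analysis failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  class(res) <- "gxe_analysis"
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' Chained starting values between nested structure fits
#'
#' Builds a full starting parameter vector for `kind` from the fits of the
#' simpler structures (uniform -> cs -> fa1), so each model starts near
#' the solution implied by its nested neighbour.
#'
#' @param kind Structure about to be fitted.
#' @param fits Named list of previous `gxe_fit`s (`uniform`, `cs`).
#' @param data The [model_data()] being fitted.
#' @return A numeric start vector, or `NULL` when no suitable previous fit
#'   exists.
#' @export
warm_start <- function(kind, fits, data) {
  nE <- length(data$envs)
  if (kind == "cs" && !is.null(fits$uniform)) {
    f <- fits$uniform
    return(c(0.95 * f$structure$sigma2_A, 0.05 * f$structure$sigma2_A,
             as.numeric(f$resid_vars)))
  }
  if (kind == "fa1" && !is.null(fits$cs)) {
    f <- fits$cs
    lam <- rep(sqrt(max(f$structure$sigma2_A, 1e-8)), nE)
    psi <- rep(max(f$structure$sigma2_AxE, 0.01 * f$structure$sigma2_A),
               nE)
    return(c(lam, psi, as.numeric(f$resid_vars)))
  }
  NULL
}

#' @export
print.gxe_analysis <- function(x, ...) {
  cat("gxe_analysis\n")
  for (s in names(x$fits)) {
    cat(sprintf("  %-8s logL = %.2f%s\n", s, x$fits[[s]]$loglik,
                if (x$fits[[s]]$converged) "" else " (not converged)"))
  }
  if (!is.null(x$avg_correlation)) {
    cat("  average env correlation (cs):", round(x$avg_correlation, 3), "\n")
  }
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' CSV tables for heritabilities, correlations, ls-means, BLUPs and CV
#' results, and a JSON summary of parameters, log-likelihoods and settings.
#'
#' @param res A `gxe_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$h2, file.path(out_dir, "heritability.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$env_correlations),
                   file.path(out_dir, "env_correlations.csv"))
  utils::write.csv(res$lsmeans, file.path(out_dir, "lsmeans.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$blup$blup),
                   file.path(out_dir, "blups.csv"))
  if (!is.null(res$cv_within)) {
    utils::write.csv(res$cv_within$results,
                     file.path(out_dir, "cv_within_location.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$cv_across)) {
    utils::write.csv(res$cv_across$results,
                     file.path(out_dir, "cv_across_location.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    settings = res$settings,
    loglik = lapply(res$fits, `[[`, "loglik"),
    converged = lapply(res$fits, `[[`, "converged"),
    lrt = res$lrt,
    avg_correlation = res$avg_correlation
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(out_dir)
}
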