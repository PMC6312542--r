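# Synthetic multi-environment study generator with known truth.
#
# Emulates the structure of a multi-location, multi-season fruit-crop
# dataset: a SNP panel with LD decaying over hundreds of kb, partial
# family structure, four locations x two seasons with Venn-style partial
# overlap of individuals, heterogeneous additive variances with near-unity
# cross-environment correlations, and heterogeneous residual variances.
# Every generator is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults describe the emulated study: 550 individuals genotyped at 1273
#' SNPs on 8 chromosomes, four locations ("balandran", "bourran", "forli",
#' "prosser") each with two seasons, partial overlap of individuals among
#' locations (only a handful present everywhere), a first-order
#' factor-analytic genetic covariance with per-environment additive
#' variances between ~26 and ~111 (squared Julian days), cross-environment
#' correlations of ~0.995 within/among the three European locations, 0.80
#' between the two Prosser seasons and ~0.89 between Prosser and Europe,
#' and per-environment residual variances of ~8-20. A planting-year fixed
#' effect applies at the first location only. Counts scale proportionally
#' when `n_G` differs from 550.
#'
#' @param n_G Number of individuals.
#' @param m Number of SNP loci.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Chromosome length (bp).
#' @param maf_range Allele-frequency range for simulated loci.
#' @param ld_decay_bp LD decay length: adjacent-haplotype latent
#'   correlation is `exp(-d / ld_decay_bp)`.
#' @param kb_per_cM Physical-to-genetic map rate used for recombination.
#' @param locations Location labels (alphabetical keeps environment
#'   ordering stable).
#' @param seasons Season labels (same for every location).
#' @param overlap Named integer vector: names are `+`-separated location
#'   sets, values are the number of individuals in exactly that set.
#'   Scaled to `n_G` if it sums elsewhere.
#' @param vG,vR Per-environment additive and residual variances
#'   (environment order: locations major, seasons minor).
#' @param common_frac Per-environment fraction of additive variance on the
#'   shared factor (loading `lambda_e = sqrt(common_frac_e * vG_e)`).
#' @param env_means Per-environment fixed means (Julian days).
#' @param obs_prob Per-environment probability that a present individual is
#'   observed that season.
#' @param planting_year `NULL` or a list with `location`, `levels`,
#'   `effects` (first effect is the reference, typically 0).
#' @param families `NULL` or a list with `n_families` and `size` (offspring
#'   per family); offspring replace the tail of the last location-unique
#'   block.
#' @param n_ancestors Size of the ancestral pool from which every study
#'   individual descends. A small pool recreates the wide dispersion of
#'   realized relationships (off-diagonal GRM variance of order 0.016)
#'   characteristic of germplasm bred from a narrow base.
#' @param resid_season_cov Optional named per-location residual covariance
#'   between seasons for the same experimental unit (default independent).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_G = 550, m = 1273, n_chrom = 8,
                       chrom_length_bp = 3e7,
                       maf_range = c(0.05, 0.5),
                       ld_decay_bp = 2.5e5,
                       kb_per_cM = 465,
                       locations = c("balandran", "bourran", "forli",
                                     "prosser"),
                       seasons = c("s1", "s2"),
                       overlap = NULL,
                       vG = c(111.3, 101.4, 60.3, 57.1, 110.4, 98.4,
                              27.6, 26.5),
                       vR = c(13.8, 10.5, 12.7, 8.1, 19.3, 20.0,
                              18.1, 17.6),
                       common_frac = c(0.995, 0.995, 0.995, 0.995,
                                       0.995, 0.995, 0.80, 0.80),
                       env_means = c(144, 148, 150, 150, 149, 152,
                                     186, 184),
                       obs_prob = c(0.86, 0.70, 0.97, 0.99, 0.89, 0.98,
                                    0.60, 0.94),
                       planting_year = list(location = "balandran",
                                            levels = c("py1", "py2"),
                                            effects = c(0, 3)),
                       families = list(n_families = round(0.178 * n_G),
                                       size = 3),
                       n_ancestors = 16,
                       resid_season_cov = NULL) {
  envs <- as.vector(t(outer(locations, seasons, paste, sep = ":")))
  nE <- length(envs)
  stopifnot(length(vG) == nE, length(vR) == nE, length(env_means) == nE,
            length(obs_prob) == nE, length(common_frac) == nE)
  if (any(vG < 0) || any(vR < 0)) stop("variances must be non-negative")
  if (ld_decay_bp <= 0) stop("ld_decay_bp must be positive")
  if (is.null(overlap)) {
    base <- c(
      "balandran+bourran+forli+prosser" = 5,
      "balandran+bourran" = 60,
      "balandran" = 6,
      "bourran+prosser" = 20,
      "bourran+forli" = 10,
      "bourran" = 98,
      "forli+prosser" = 5,
      "forli" = 36,
      "prosser" = 310
    )
    if (!identical(locations,
                   c("balandran", "bourran", "forli", "prosser"))) {
      # generic fallback: equal split of unique blocks plus a small
      # everywhere-set
      k <- length(locations)
      base <- stats::setNames(
        c(max(2, round(0.01 * n_G)), rep(1, k)),
        c(paste(locations, collapse = "+"), locations)
      )
    }
    overlap <- base
  }
  if (sum(overlap) != n_G) { # proportional rescale, remainder to largest
    sc <- round(overlap * n_G / sum(overlap))
    sc[which.max(sc)] <- sc[which.max(sc)] + n_G - sum(sc)
    overlap <- sc
  }
  lam <- sqrt(common_frac * vG)
  structure(
    list(
      n_G = n_G, m = m, n_chrom = n_chrom,
      chrom_length_bp = chrom_length_bp, maf_range = maf_range,
      ld_decay_bp = ld_decay_bp, kb_per_cM = kb_per_cM,
      locations = locations, seasons = seasons, envs = envs,
      overlap = overlap,
      structure = env_cov_structure("fa1", Lambda = lam,
                                    Psi = vG - lam^2, envs = envs),
      vG = stats::setNames(vG, envs), vR = stats::setNames(vR, envs),
      env_means = stats::setNames(env_means, envs),
      obs_prob = stats::setNames(obs_prob, envs),
      planting_year = planting_year,
      families = families,
      n_ancestors = n_ancestors,
      resid_season_cov = resid_season_cov
    ),
    class = "sim_config"
  )
}

# evenly spread loci with jittered spacing across chromosomes
sim_map <- function(cfg, seed) {
  per <- diff(round(seq(0, cfg$m, length.out = cfg$n_chrom + 1)))
  with_seed(derive_seed(seed, "map"), {
    rows <- lapply(seq_len(cfg$n_chrom), function(ch) {
      k <- per[ch]
      pos <- sort(round(stats::runif(k, 1, cfg$chrom_length_bp)))
      pos <- pos + seq_len(k) # break exact ties deterministically
      data.frame(chrom = as.character(ch), pos_bp = pos,
                 stringsAsFactors = FALSE)
    })
    map <- do.call(rbind, rows)
    map$locus <- sprintf("snp%04d", seq_len(nrow(map)))
    map[, c("locus", "chrom", "pos_bp")]
  })
}

#' Simulate founder genotypes with distance-decaying LD
#'
#' Founder haplotypes follow a first-order Gaussian-copula chain along each
#' chromosome: a latent AR(1) process with adjacent-locus correlation
#' `exp(-d / ld_decay_bp)` is thresholded at each locus's allele frequency.
#' Dosages are the sum of two independent haplotypes. Deterministic per
#' seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param n Number of founders (defaults to `cfg$n_G`).
#' @param ids Individual labels.
#' @return A list with `genotypes` ([genotype_matrix()]), `haplotypes`
#'   (`2n x m` 0/1 matrix, rows `id|1`, `id|2`) and `p` (true allele
#'   frequencies).
#' @export
simulate_genotypes <- function(cfg = sim_config(), seed = 1, n = NULL,
                               ids = NULL) {
  if (cfg$ld_decay_bp <= 0) stop("ld_decay_bp must be positive")
  if (is.null(n)) n <- cfg$n_G
  stopifnot(n >= 2, cfg$m >= 2)
  if (is.null(ids)) ids <- sprintf("g%04d", seq_len(n))
  map <- sim_map(cfg, seed)
  m <- nrow(map)
  H <- matrix(0L, 2L * n, m)
  with_seed(derive_seed(seed, "founders"), {
    p <- stats::runif(m, cfg$maf_range[1], 1 - cfg$maf_range[1])
    thr <- stats::qnorm(p)
    for (ch in unique(map$chrom)) {
      jj <- which(map$chrom == ch)
      d <- diff(map$pos_bp[jj])
      r <- exp(-d / cfg$ld_decay_bp)
      z <- stats::rnorm(2L * n)
      H[, jj[1L]] <- as.integer(z < thr[jj[1L]])
      for (t in seq_along(d)) {
        z <- r[t] * z + sqrt(1 - r[t]^2) * stats::rnorm(2L * n)
        H[, jj[t + 1L]] <- as.integer(z < thr[jj[t + 1L]])
      }
    }
    dos <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    dimnames(dos) <- list(ids, map$locus)
    rownames(H) <- paste(rep(ids, each = 2L), 1:2, sep = "|")
    colnames(H) <- map$locus
    list(genotypes = genotype_matrix(dos, map), haplotypes = H, p = p)
  })
}

# one recombined gamete from a phased parent
sim_gamete <- function(H, id, map, kb_per_cM) {
  h1 <- H[paste(id, 1, sep = "|"), ]
  h2 <- H[paste(id, 2, sep = "|"), ]
  g <- integer(length(h1))
  for (ch in unique(map$chrom)) {
    jj <- which(map$chrom == ch)
    d_morgan <- diff(map$pos_bp[jj]) / 1000 / kb_per_cM / 100
    r <- 0.5 * (1 - exp(-2 * d_morgan)) # Haldane, no interference
    sw <- stats::runif(length(r)) < r
    # parental-strand path: start strand flipped at each crossover
    path <- (sample(0:1, 1L) + cumsum(c(0L, as.integer(sw)))) %% 2L
    g[jj] <- ifelse(path == 0L, h1[jj], h2[jj])
  }
  g
}

#' Simulate offspring families by Mendelian transmission
#'
#' Each offspring receives one recombined gamete from each parent;
#' recombination fractions follow Haldane's map function at the configured
#' kb-per-cM rate (no interference). The pedigree is recorded.
#'
#' @param founders Result of [simulate_genotypes()] (haplotypes required).
#' @param crosses Data.frame with `parent1`, `parent2`, `n_offspring`;
#'   selfing (`parent1 == parent2`) is allowed only when `allow_selfing`.
#' @param seed Integer seed.
#' @param ids Offspring labels (default `o0001`, ...).
#' @param allow_selfing Permit self-crosses?
#' @return A list with `genotypes` (offspring [genotype_matrix()]),
#'   `haplotypes`, and `pedigree` (`id`, `parent1`, `parent2`).
#' @export
simulate_families <- function(founders, crosses, seed = 1, ids = NULL,
                              allow_selfing = FALSE) {
  H <- founders$haplotypes
  map <- founders$genotypes$map
  kb <- attr(founders, "kb_per_cM")
  if (is.null(kb)) kb <- 465
  n_off <- sum(crosses$n_offspring)
  if (is.null(ids)) ids <- sprintf("o%04d", seq_len(n_off))
  stopifnot(length(ids) == n_off)
  if (!allow_selfing && any(crosses$parent1 == crosses$parent2)) {
    stop("self-crosses not allowed unless allow_selfing = TRUE")
  }
  with_seed(derive_seed(seed, "families"), {
    dos <- matrix(0L, n_off, nrow(map), dimnames = list(ids, map$locus))
    Hoff <- matrix(0L, 2L * n_off, nrow(map),
                   dimnames = list(paste(rep(ids, each = 2L), 1:2,
                                         sep = "|"),
                                   map$locus))
    ped <- data.frame(id = ids, parent1 = NA_character_,
                      parent2 = NA_character_, stringsAsFactors = FALSE)
    k <- 0L
    for (cr in seq_len(nrow(crosses))) {
      for (o in seq_len(crosses$n_offspring[cr])) {
        k <- k + 1L
        g1 <- sim_gamete(H, crosses$parent1[cr], map, kb)
        g2 <- sim_gamete(H, crosses$parent2[cr], map, kb)
        dos[k, ] <- g1 + g2
        Hoff[2L * k - 1L, ] <- g1
        Hoff[2L * k, ] <- g2
        ped$parent1[k] <- crosses$parent1[cr]
        ped$parent2[k] <- crosses$parent2[cr]
      }
    }
    list(genotypes = genotype_matrix(dos, map), haplotypes = Hoff,
         pedigree = ped)
  })
}

#' Simulate true breeding values under a G x E covariance structure
#'
#' Marker-effect route: each locus gets an effect vector across
#' environments drawn from the structure's covariance, and breeding values
#' are centered dosages times effects, so the covariance of breeding
#' values is (in expectation) exactly `G_AxE (x) G_A` — the model later
#' fitted to the data. The default `"model"` scaling sets the per-locus
#' effect variance so that the additive variance parameter (the quantity
#' REML estimates, referenced to the relationship-matrix scale) equals the
#' target; `"realized"` scaling instead forces the sample variance of
#' breeding values across the panel to the target exactly, which conflates
#' scale with relatedness when the panel contains family structure.
#'
#' @param G A complete [genotype_matrix()].
#' @param structure An [env_cov_structure()].
#' @param target_vG Per-environment target additive variances (default the
#'   structure's implied diagonal).
#' @param seed Integer seed.
#' @param scaling `"model"` (default) or `"realized"` (see Details).
#' @return `n_G x n_E` matrix of true breeding values (individual x
#'   environment), centered per environment.
#' @export
simulate_true_bvs <- function(G, structure, target_vG = NULL, seed = 1,
                              scaling = c("model", "realized")) {
  scaling <- match.arg(scaling)
  Sig <- env_cov_matrix(structure)
  nE <- nrow(Sig)
  if (is.null(target_vG)) target_vG <- diag(Sig)
  stopifnot(length(target_vG) == nE)
  d <- G$dosages
  if (anyNA(d)) stop("breeding values require a complete matrix")
  Zc <- scale(d, center = TRUE, scale = FALSE)
  if (all(abs(Zc) < 1e-12)) stop("zero-variance panel")
  m <- ncol(d)
  # correlation shape of the structure; PSD-tolerant square root
  ev <- eigen((Sig + t(Sig)) / 2, symmetric = TRUE)
  pos <- pmax(ev$values, 0)
  Sroot <- ev$vectors %*% diag(sqrt(pos), nE)
  bv <- with_seed(derive_seed(seed, "bvs"), {
    eff <- matrix(stats::rnorm(m * nE), m, nE) %*% t(Sroot)
    Zc %*% eff
  })
  if (scaling == "model") {
    # sum over loci of dosage variances: the VanRaden denominator of the
    # causal panel, so that var(BV_e) = target on the G_A diagonal scale
    S <- sum(apply(d, 2L, pop_var))
    if (S <= 0) stop("zero-variance panel")
    sc <- sqrt(target_vG / (pmax(diag(Sig), .Machine$double.xmin) * S))
    sc[diag(Sig) == 0] <- 0
    bv <- sweep(bv, 2L, sc, `*`)
  } else {
    v <- apply(bv, 2L, pop_var)
    v[v <= 0] <- 1
    bv <- sweep(bv, 2L, sqrt(target_vG / v), `*`)
  }
  bv <- sweep(bv, 2L, colMeans(bv), `-`)
  dimnames(bv) <- list(rownames(d),
                       if (!is.null(structure$envs)) structure$envs else
                         paste0("env", seq_len(nE)))
  bv
}

# assign individuals to location sets per the overlap design
overlap_assignment <- function(cfg, ids) {
  stopifnot(length(ids) == sum(cfg$overlap))
  sets <- strsplit(names(cfg$overlap), "+", fixed = TRUE)
  out <- list()
  k <- 0L
  for (i in seq_along(sets)) {
    take <- ids[k + seq_len(cfg$overlap[i])]
    k <- k + cfg$overlap[i]
    for (l in sets[[i]]) out[[l]] <- c(out[[l]], take)
  }
  out
}

#' Simulate phenotypes from breeding values and the trial design
#'
#' Emits one record per observed (individual, location, season): the
#' environment mean, plus the planting-year effect where configured, plus
#' the true breeding value, plus a residual drawn per experimental unit
#' from the location's season covariance (independent seasons by default).
#' Observation incidence follows the per-environment observation
#' probabilities; the overlap design decides which individuals exist at
#' each location.
#'
#' @param bvs Breeding-value matrix from [simulate_true_bvs()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `pheno` (a `phenotype_table`), `assignment`
#'   (location -> individual ids) and `truth` (per-record mean, breeding
#'   value, planting-year effect and residual, so that
#'   `y = mean + py + bv + residual` reconstructs exactly).
#' @export
simulate_phenotypes <- function(bvs, cfg, seed = 1) {
  ids <- rownames(bvs)
  assignment <- overlap_assignment(cfg, ids)
  if (!length(assignment)) stop("empty overlap design")
  nS <- length(cfg$seasons)
  py_of <- NULL
  if (!is.null(cfg$planting_year)) {
    pl <- cfg$planting_year
    ids_at <- assignment[[pl$location]]
    py_of <- with_seed(derive_seed(seed, "planting_year"), {
      stats::setNames(sample(pl$levels, length(ids_at), replace = TRUE),
                      ids_at)
    })
  }
  rows <- with_seed(derive_seed(seed, "phenotypes"), {
    out <- list()
    for (l in cfg$locations) {
      Rj <- diag(cfg$vR[paste(l, cfg$seasons, sep = ":")], nS)
      dimnames(Rj) <- list(cfg$seasons, cfg$seasons)
      if (!is.null(cfg$resid_season_cov) &&
          !is.na(cfg$resid_season_cov[l])) {
        Rj[upper.tri(Rj)] <- cfg$resid_season_cov[l]
        Rj[lower.tri(Rj)] <- cfg$resid_season_cov[l]
      }
      chR <- chol(Rj)
      for (id in assignment[[l]]) {
        resid <- as.numeric(crossprod(chR, stats::rnorm(nS)))
        obs <- stats::runif(nS) <
          cfg$obs_prob[paste(l, cfg$seasons, sep = ":")]
        for (s in seq_len(nS)) {
          if (!obs[s]) next
          env <- paste(l, cfg$seasons[s], sep = ":")
          pyeff <- 0
          pylev <- NA_character_
          if (!is.null(py_of) && l == cfg$planting_year$location) {
            pylev <- py_of[[id]]
            pyeff <- cfg$planting_year$effects[
              match(pylev, cfg$planting_year$levels)]
          }
          out[[length(out) + 1L]] <- data.frame(
            Location = l, Year = cfg$seasons[s], REF_ID = id,
            Experimental.unit = paste(l, id, sep = ":"),
            Observation.unit = paste(l, id, cfg$seasons[s], sep = ":"),
            Planting.date = pylev,
            y = cfg$env_means[env] + pyeff + bvs[id, env] + resid[s],
            mean_part = unname(cfg$env_means[env]),
            py_part = pyeff, bv_part = bvs[id, env],
            resid_part = resid[s],
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out
  })
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  truth <- rec[, c("REF_ID", "Location", "Year", "mean_part", "py_part",
                   "bv_part", "resid_part")]
  pheno <- rec[, c("Location", "Year", "REF_ID", "Experimental.unit",
                   "Observation.unit", "Planting.date", "y")]
  for (f in setdiff(phenotype_fields(), names(pheno))) pheno[[f]] <- NA
  pheno <- pheno[, c(phenotype_fields(),
                     setdiff(names(pheno), phenotype_fields()))]
  class(pheno) <- c("phenotype_table", "data.frame")
  list(pheno = pheno, assignment = assignment, truth = truth)
}

#' Simulate a complete multi-environment study
#'
#' Genotypes (founders plus optional families), true breeding values under
#' the configured G x E structure, and unbalanced phenotypes, with a full
#' truth record for recovery testing.
#'
#' @param cfg A [sim_config()].
#' @param seed Master integer seed; all stages derive their streams from
#'   it.
#' @return A list of class `simulated_study`: `genotypes`, `pedigree` (or
#'   `NULL`), `bvs` (true breeding values), `pheno`, `assignment`, `truth`
#'   (record-level decomposition), `cfg`, `seed`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1) {
  n_off <- if (is.null(cfg$families)) 0L else {
    cfg$families$n_families * cfg$families$size
  }
  n_base <- cfg$n_G - n_off
  stopifnot(n_base >= 2)
  # A narrow ancestral pool recreates the dispersion of realized
  # relationships seen in long-bred perennial germplasm: every study
  # individual descends from a handful of shared ancestors.
  ancestors <- simulate_genotypes(
    cfg, seed, n = cfg$n_ancestors,
    ids = sprintf("anc%03d", seq_len(cfg$n_ancestors))
  )
  attr(ancestors, "kb_per_cM") <- cfg$kb_per_cM
  anc_ids <- rownames(ancestors$genotypes$dosages)
  base_pairs <- with_seed(derive_seed(seed, "base_pairs"), {
    t(vapply(seq_len(n_base), function(i) sample(anc_ids, 2L),
             character(2)))
  })
  base <- simulate_families(
    ancestors,
    data.frame(parent1 = base_pairs[, 1L], parent2 = base_pairs[, 2L],
               n_offspring = 1L, stringsAsFactors = FALSE),
    seed = seed, ids = sprintf("g%04d", seq_len(n_base))
  )
  pedigree <- rbind(
    data.frame(id = anc_ids, parent1 = NA_character_,
               parent2 = NA_character_, stringsAsFactors = FALSE),
    base$pedigree
  )
  geno <- base$genotypes
  if (n_off > 0L) {
    base_pool <- list(genotypes = base$genotypes,
                      haplotypes = base$haplotypes)
    attr(base_pool, "kb_per_cM") <- cfg$kb_per_cM
    pairs <- with_seed(derive_seed(seed, "crosses"), {
      t(vapply(seq_len(cfg$families$n_families),
               function(i) sample(rownames(base$genotypes$dosages), 2L),
               character(2)))
    })
    crosses <- data.frame(parent1 = pairs[, 1L], parent2 = pairs[, 2L],
                          n_offspring = cfg$families$size,
                          stringsAsFactors = FALSE)
    off <- simulate_families(base_pool, crosses, seed = seed)
    geno <- genotype_matrix(rbind(base$genotypes$dosages,
                                  off$genotypes$dosages),
                            base$genotypes$map)
    pedigree <- rbind(pedigree, off$pedigree)
  }
  bvs <- simulate_true_bvs(geno, cfg$structure,
                           target_vG = as.numeric(cfg$vG), seed = seed)
  ph <- simulate_phenotypes(bvs, cfg, seed)
  structure(
    list(genotypes = geno, pedigree = pedigree, bvs = bvs,
         pheno = ph$pheno, assignment = ph$assignment, truth = ph$truth,
         cfg = cfg, seed = seed),
    class = "simulated_study"
  )
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("simulated_study:", nrow(x$genotypes$dosages), "individuals,",
      ncol(x$genotypes$dosages), "loci,", nrow(x$pheno), "records,",
      length(x$cfg$envs), "environments (seed", x$seed, ")\n")
  invisible(x)
}

#' Compare estimated parameters and predictions against simulation truth
#'
#' @param truth A `simulated_study`.
#' @param fit A `gxe_fit` on the study's data.
#' @param blup Optional `gxe_blup` with predictions to score against true
#'   breeding values.
#' @param cv Optional `cv_result` to juxtapose with theoretical accuracy
#'   `sqrt(h2)`.
#' @return A list of class `recovery_report`: `h2` (true, estimated, bias
#'   per environment), `correlation_error` (estimated minus true implied
#'   correlations), `bv_accuracy` (correlation of predicted and true
#'   breeding values per environment, if `blup` given), `cv` (PA beside
#'   `sqrt(h2)`, if given). Serializable with [write_recovery_report()].
#' @export
truth_vs_estimate_report <- function(truth, fit, blup = NULL, cv = NULL) {
  cfg <- truth$cfg
  if (!identical(sort(cfg$envs), sort(fit$envs))) {
    stop("environment sets of truth and fit differ")
  }
  true_h2 <- heritability(as.numeric(cfg$vG), as.numeric(cfg$vR))
  est <- heritability_table(fit)
  est <- est[match(cfg$envs, est$env), ]
  h2 <- data.frame(
    env = cfg$envs, true = true_h2, estimated = est$h2,
    bias = est$h2 - true_h2, stringsAsFactors = FALSE
  )
  true_corr <- implied_env_correlations(cfg$structure)
  est_corr <- implied_env_correlations(fit$structure)[cfg$envs, cfg$envs]
  bv_acc <- NULL
  if (!is.null(blup)) {
    ids <- intersect(rownames(truth$bvs), rownames(blup$blup))
    bv_acc <- vapply(cfg$envs, function(e) {
      stats::cor(truth$bvs[ids, e], blup$blup[ids, e])
    }, numeric(1))
  }
  cv_tab <- NULL
  if (!is.null(cv)) {
    cv_tab <- cv$results
    envkey <- paste(cv_tab$location, cv_tab$season, sep = ":")
    cv_tab$sqrt_h2 <- sqrt(true_h2[match(envkey, cfg$envs)])
  }
  structure(
    list(h2 = h2, correlation_error = est_corr - true_corr,
         bv_accuracy = bv_acc, cv = cv_tab),
    class = "recovery_report"
  )
}

#' Serialize / restore a recovery report (lossless JSON round-trip)
#'
#' @param report A `recovery_report`.
#' @param path JSON file path.
#' @return `write_recovery_report` returns `path`; `read_recovery_report`
#'   the restored report.
#' @export
write_recovery_report <- function(report, path) {
  obj <- list(
    h2 = report$h2,
    correlation_error = list(
      envs = rownames(report$correlation_error),
      values = unname(as.matrix(report$correlation_error))
    ),
    bv_accuracy = if (is.null(report$bv_accuracy)) NULL else {
      list(envs = names(report$bv_accuracy),
           values = unname(report$bv_accuracy))
    },
    cv = report$cv
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_recovery_report
#' @export
read_recovery_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ce <- as.matrix(obj$correlation_error$values)
  dimnames(ce) <- list(obj$correlation_error$envs,
                       obj$correlation_error$envs)
  structure(
    list(
      h2 = as.data.frame(obj$h2),
      correlation_error = ce,
      bv_accuracy = if (is.null(obj$bv_accuracy)) NULL else {
        stats::setNames(obj$bv_accuracy$values, obj$bv_accuracy$envs)
      },
      cv = if (is.null(obj$cv)) NULL else as.data.frame(obj$cv)
    ),
    class = "recovery_report"
  )
}
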