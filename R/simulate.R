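#' Configuration for synthetic genebank trials
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the structure of a historical multi-year genebank screening: one dominant
#' year holding most records, additional years with partial coverage (so
#' that single-record accessions arise naturally), year-specific residual
#' variances, a small rate of gross outliers, a positive lysine--protein
#' genetic correlation with thousand grain weight (TGW) negatively
#' correlated with both, and a collecting-site altitude coupled to the
#' genetic value for lysine.
#'
#' @param n_accessions Number of accessions (genotypes).
#' @param n_markers Number of biallelic markers.
#' @param maf_range Length-2 numeric in (0, 0.5]: per-marker allele
#'   frequencies are drawn uniformly from this range.
#' @param year_plan Named numeric vector mapping year label to the fraction
#'   of accessions tested in that year (each in (0, 1]).
#' @param heritability_target Plot-based heritability the generator
#'   calibrates exactly: `var(g) / (var(g) + mean(year_error_sds^2))`.
#' @param year_effect_sd Standard deviation of the random year effects
#'   (trait units).
#' @param year_error_sds Per-year residual standard deviations (recycled or
#'   named by year). Default: evenly spaced between 0.7 and 1.3.
#' @param outlier_rate Fraction of records contaminated as gross outliers.
#' @param outlier_shift Size of the contamination in multiples of the
#'   record's year-specific residual SD (sign random).
#' @param trait_correlation_targets Named numeric with entries
#'   `lysine_protein`, `tgw_protein`, `tgw_lysine`: intended genetic
#'   correlations among the three traits.
#' @param epistasis_fraction Fraction of the genetic variance that is
#'   additive-by-additive.
#' @param n_epistatic_pairs Number of random marker pairs carrying the
#'   epistatic interaction effects.
#' @param altitude_coupling Correlation of collecting-site altitude with the
#'   genetic value for lysine.
#' @param seed Integer seed; the whole generator is deterministic given the
#'   configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_accessions = 50, n_markers = 100, seed = 7)
#' geno <- simulate_genotypes(cfg)
#' dim(geno)
sim_config <- function(n_accessions = 500,
                       n_markers = 1000,
                       maf_range = c(0.05, 0.5),
                       year_plan = c("1970" = 0.90, "1972" = 0.50,
                                     "1974" = 0.40, "1976" = 0.35,
                                     "1978" = 0.25),
                       heritability_target = 0.5,
                       year_effect_sd = 1,
                       year_error_sds = NULL,
                       outlier_rate = 0.013,
                       outlier_shift = 6,
                       trait_correlation_targets = c(lysine_protein = 0.63,
                                                     tgw_protein = -0.278,
                                                     tgw_lysine = -0.266),
                       epistasis_fraction = 0,
                       n_epistatic_pairs = 200,
                       altitude_coupling = 0.5,
                       seed = 1L) {
  check_count(n_accessions, "n_accessions", min = 2L)
  check_count(n_markers, "n_markers", min = 1L)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop_bad_arg("`maf_range` must be an increasing pair within (0, 0.5]",
                 class = "genebankgp_config_error")
  }
  if (is.null(names(year_plan)) || any(!nzchar(names(year_plan)))) {
    stop_bad_arg("`year_plan` must be named by year labels",
                 class = "genebankgp_config_error")
  }
  if (any(year_plan <= 0) || any(year_plan > 1)) {
    stop_bad_arg("`year_plan` fractions must lie in (0, 1]",
                 class = "genebankgp_config_error")
  }
  check_number(heritability_target, "heritability_target", 0, 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(year_effect_sd, "year_effect_sd", 0)
  n_years <- length(year_plan)
  if (is.null(year_error_sds)) {
    year_error_sds <- if (n_years == 1L) 1 else seq(0.7, 1.3, length.out = n_years)
  }
  year_error_sds <- rep_len(year_error_sds, n_years)
  if (is.null(names(year_error_sds))) names(year_error_sds) <- names(year_plan)
  if (any(year_error_sds <= 0)) {
    stop_bad_arg("`year_error_sds` must all be > 0",
                 class = "genebankgp_config_error")
  }
  check_number(outlier_rate, "outlier_rate", 0, 1)
  check_number(outlier_shift, "outlier_shift", 0)
  check_number(epistasis_fraction, "epistasis_fraction", 0, 1,
               closed_upper = FALSE)
  check_count(n_epistatic_pairs, "n_epistatic_pairs", min = 1L)
  check_number(altitude_coupling, "altitude_coupling", -1, 1)
  needed <- c("lysine_protein", "tgw_protein", "tgw_lysine")
  if (!all(needed %in% names(trait_correlation_targets))) {
    stop_bad_arg(paste("`trait_correlation_targets` needs entries",
                       paste(needed, collapse = ", ")),
                 class = "genebankgp_config_error")
  }
  structure(list(
    n_accessions = as.integer(n_accessions),
    n_markers = as.integer(n_markers),
    maf_range = as.numeric(maf_range),
    year_plan = year_plan,
    n_years = n_years,
    heritability_target = heritability_target,
    year_effect_sd = year_effect_sd,
    year_error_sds = year_error_sds,
    outlier_rate = outlier_rate,
    outlier_shift = outlier_shift,
    trait_correlation_targets = trait_correlation_targets[needed],
    epistasis_fraction = epistasis_fraction,
    n_epistatic_pairs = as.integer(n_epistatic_pairs),
    altitude_coupling = altitude_coupling,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a biallelic genotype matrix
#'
#' Draws per-marker alternative-allele frequencies uniformly from
#' `config$maf_range` and samples genotype codes 0/1/2 per accession.
#' Accessions are inbred by default (no heterozygotes), matching a selfing
#' crop; heterozygosity and missingness can be injected to exercise the
#' marker filters.
#'
#' @param config A [sim_config()].
#' @param missing_rate Fraction of calls set missing (`NA`), uniformly.
#' @param het_rate Either a fraction of heterozygous calls per marker, or
#'   `"hwe"` for Hardy-Weinberg heterozygosity `2p(1-p)` per marker.
#' @return Integer matrix (accessions x markers) with dimnames, possibly
#'   containing `NA`.
#' @export
simulate_genotypes <- function(config, missing_rate = 0, het_rate = 0) {
  stopifnot(inherits(config, "sim_config"))
  check_number(missing_rate, "missing_rate", 0, 1, closed_upper = FALSE)
  set.seed(config$seed)
  n <- config$n_accessions
  m <- config$n_markers
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  hwe <- identical(het_rate, "hwe")
  if (!hwe) check_number(het_rate, "het_rate", 0, 1)
  h <- if (hwe) 2 * p * (1 - p) else pmin(het_rate, 2 * pmin(p, 1 - p))
  # P(2) = p - h/2, P(1) = h, P(0) = 1 - p - h/2 keeps allele freq at p
  codes <- vapply(seq_len(m), function(k) {
    sample(c(0L, 1L, 2L), n, replace = TRUE,
           prob = c(1 - p[k] - h[k] / 2, h[k], p[k] - h[k] / 2))
  }, integer(n))
  dimnames(codes) <- list(sprintf("ACC%04d", seq_len(n)),
                          sprintf("M%05d", seq_len(m)))
  if (missing_rate > 0) {
    codes[runif(length(codes)) < missing_rate] <- NA_integer_
  }
  codes
}

# additive genetic values with exactly the requested SD; returns list with
# values, per-marker effects on centered codes, and the centering vector
.simulate_additive <- function(geno, target_sd) {
  m <- ncol(geno)
  center <- colMeans(geno)
  Zc <- sweep(geno, 2L, center)
  alpha <- rnorm(m)
  g <- drop(Zc %*% alpha)
  s <- stats::sd(g)
  scale_fac <- if (s > 0 && target_sd > 0) target_sd / s else 0
  list(values = g * scale_fac, effects = setNames(alpha * scale_fac, colnames(geno)),
       center = center)
}

# additive-by-additive values over random marker pairs, exact SD; the
# component is residualized against the additive values so the two parts
# add orthogonally and the total genetic variance calibrates exactly
.simulate_epistatic <- function(geno, n_pairs, target_sd, additive = NULL) {
  if (target_sd <= 0) {
    return(list(values = rep(0, nrow(geno)), pairs = NULL, effects = NULL))
  }
  m <- ncol(geno)
  Zc <- sweep(geno, 2L, colMeans(geno))
  pairs <- cbind(sample.int(m, n_pairs, replace = TRUE),
                 sample.int(m, n_pairs, replace = TRUE))
  gamma <- rnorm(n_pairs)
  W <- Zc[, pairs[, 1], drop = FALSE] * Zc[, pairs[, 2], drop = FALSE]
  v <- drop(W %*% gamma)
  v <- v - mean(v)
  if (!is.null(additive) && stats::var(additive) > 0) {
    v <- v - additive * stats::cov(v, additive) / stats::var(additive)
  }
  s <- stats::sd(v)
  fac <- if (s > 0) target_sd / s else 0
  list(values = v * fac, pairs = pairs, effects = gamma * fac)
}

# draw year membership; returns list year -> accession ids
.draw_year_plan <- function(accessions, year_plan) {
  lapply(year_plan, function(frac) {
    sort(sample(accessions, max(2L, round(frac * length(accessions)))))
  })
}

.assemble_records <- function(membership, trait, mu, g, year_effects,
                              year_sds, outlier_rate, outlier_shift) {
  rows <- purrr::imap(membership, function(acc, yr) {
    tibble(accession_id = acc, year = yr, trait = trait,
           value = mu + g[acc] + year_effects[yr] +
             rnorm(length(acc), 0, year_sds[yr]))
  })
  tab <- dplyr::bind_rows(rows)
  n_rec <- nrow(tab)
  flags <- rep(FALSE, n_rec)
  n_out <- round(outlier_rate * n_rec)
  if (n_out > 0) {
    idx <- sample.int(n_rec, n_out)
    flags[idx] <- TRUE
    shift <- outlier_shift * year_sds[tab$year[idx]] *
      sample(c(-1, 1), n_out, replace = TRUE)
    tab$value[idx] <- tab$value[idx] + shift
  }
  list(table = tab, outlier_flags = flags)
}

.check_year_overlap <- function(membership) {
  yrs <- names(membership)
  if (length(yrs) < 2L) return(invisible(NULL))
  for (j in yrs) {
    others <- unique(unlist(membership[setdiff(yrs, j)]))
    if (!any(membership[[j]] %in% others)) {
      rlang::warn(sprintf(
        "year %s shares no accession with any other year; trim_records() will drop it", j))
    }
  }
  invisible(NULL)
}

#' Simulate a multi-year unbalanced phenotype trial
#'
#' Generates records `value = mu + g_i + a_j + e_ij` where the genetic
#' values `g_i` derive from marker effects (plus an optional
#' additive-by-additive share over random marker pairs), `a_j` are random
#' year effects and `e_ij` have year-specific residual variances. A fraction
#' of records is contaminated by gross outliers. The genetic variance is
#' rescaled exactly so that
#' `var(g) / (var(g) + mean(year_error_sds^2)) = heritability_target`
#' (the plot-based heritability).
#'
#' @param genotypes Matrix from [simulate_genotypes()] (no missing codes).
#' @param config A [sim_config()]; `config$year_plan` must span at least two
#'   years.
#' @param trait,mu Trait label and general mean of the records.
#' @return A list with `phenotypes` (tibble `accession_id, year, trait,
#'   value`) and `truth` (class `synthetic_truth`: true breeding values,
#'   marker effects and centering vector, epistatic values, year effects,
#'   outlier flags aligned with the phenotype rows, and the variance
#'   components used).
#' @export
simulate_trial <- function(genotypes, config, trait = "trait", mu = 0) {
  stopifnot(inherits(config, "sim_config"))
  check_genotypes(genotypes)
  if (config$n_years < 2L) {
    stop_bad_arg("`year_plan` must define at least two years",
                 class = "genebankgp_config_error")
  }
  set.seed(config$seed + 1L)
  sigma_e2_bar <- mean(config$year_error_sds^2)
  h2 <- config$heritability_target
  sigma_g2 <- h2 / (1 - h2) * sigma_e2_bar
  phi <- config$epistasis_fraction
  add <- .simulate_additive(genotypes, sqrt((1 - phi) * sigma_g2))
  epi <- .simulate_epistatic(genotypes, config$n_epistatic_pairs,
                             sqrt(phi * sigma_g2), additive = add$values)
  g <- setNames(add$values + epi$values, rownames(genotypes))
  year_effects <- setNames(
    if (config$year_effect_sd > 0)
      rnorm(config$n_years, 0, config$year_effect_sd) else rep(0, config$n_years),
    names(config$year_plan))
  membership <- .draw_year_plan(rownames(genotypes), config$year_plan)
  .check_year_overlap(membership)
  rec <- .assemble_records(membership, trait, mu, g, year_effects,
                           config$year_error_sds,
                           config$outlier_rate, config$outlier_shift)
  truth <- structure(list(
    true_breeding_values = g,
    marker_effects = add$effects,
    marker_center = add$center,
    epistatic_values = setNames(epi$values, rownames(genotypes)),
    epistatic_pairs = epi$pairs,
    year_effects = year_effects,
    outlier_flags = rec$outlier_flags,
    sigma_g2 = sigma_g2,
    sigma_e2_by_year = setNames(config$year_error_sds^2,
                                names(config$year_plan)),
    mu = mu
  ), class = "synthetic_truth")
  list(phenotypes = rec$table, truth = truth)
}

# trait scales mirroring the magnitudes of a historical wheat quality
# screen: protein content (%), lysine content (per mille), TGW (g)
.trait_scales <- function() {
  tibble(trait = c("protein", "lysine", "tgw"),
         mu = c(17.61, 4.17, 45),
         sigma_e = c(sqrt(2.679), sqrt(0.168), 2))
}

#' Simulate three genetically correlated seed traits
#'
#' Generates protein content, lysine content and TGW for the same set of
#' accessions with a target genetic correlation structure (shared-factor
#' construction: per-marker effect vectors drawn from a trivariate normal
#' with the target correlation). Each trait gets its own multi-year trial
#' with year-specific residual SDs scaled to the trait's units; TGW is only
#' recorded for a subset of accessions, as is typical when seed-weight data
#' comes from a different campaign. Also generates a collecting-site
#' altitude correlated with the genetic value for lysine.
#'
#' @inheritParams simulate_trial
#' @param tgw_coverage Fraction of accessions with TGW records.
#' @return A list with `phenotypes` (named list of three tibbles:
#'   `protein`, `lysine`, `tgw`) and `truth` (class `synthetic_truth`, with
#'   per-trait breeding values, the implied partial-regression coefficients
#'   `adjustment_coefficients`, and `altitude` in metres).
#' @export
simulate_correlated_traits <- function(genotypes, config, tgw_coverage = 0.6) {
  stopifnot(inherits(config, "sim_config"))
  check_genotypes(genotypes)
  check_number(tgw_coverage, "tgw_coverage", 0, 1, closed_lower = FALSE)
  tg <- config$trait_correlation_targets
  Sigma <- matrix(c(1, tg["lysine_protein"], tg["tgw_protein"],
                    tg["lysine_protein"], 1, tg["tgw_lysine"],
                    tg["tgw_protein"], tg["tgw_lysine"], 1),
                  3, 3, dimnames = list(c("protein", "lysine", "tgw"),
                                        c("protein", "lysine", "tgw")))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop_bad_arg("`trait_correlation_targets` do not form a positive-definite correlation structure",
                 class = "genebankgp_config_error")
  }
  set.seed(config$seed + 2L)
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  scales <- .trait_scales()
  h2 <- config$heritability_target
  center <- colMeans(genotypes)
  Zc <- sweep(genotypes, 2L, center)
  E <- matrix(rnorm(m * 3), m, 3) %*% ch   # correlated marker effects
  G_raw <- Zc %*% E
  sd_mult <- config$year_error_sds / sqrt(mean(config$year_error_sds^2))
  bv <- list(); effects <- list(); tables <- list(); flags <- list()
  year_effects_all <- list()
  year_sds_all <- list()
  membership <- .draw_year_plan(rownames(genotypes), config$year_plan)
  tgw_set <- sort(sample(rownames(genotypes), round(tgw_coverage * n)))
  for (t in scales$trait) {
    sc <- scales[scales$trait == t, ]
    sigma_g <- sqrt(h2 / (1 - h2)) * sc$sigma_e
    col <- G_raw[, t]
    fac <- if (stats::sd(col) > 0) sigma_g / stats::sd(col) else 0
    g_t <- (col - mean(col)) * fac
    bv[[t]] <- setNames(g_t, rownames(genotypes))
    effects[[t]] <- setNames(E[, t] * fac, colnames(genotypes))
    year_sds <- setNames(sc$sigma_e * sd_mult, names(config$year_plan))
    year_eff <- setNames(
      if (config$year_effect_sd > 0)
        rnorm(config$n_years, 0, config$year_effect_sd * sc$sigma_e) else
          rep(0, config$n_years),
      names(config$year_plan))
    memb_t <- if (t == "tgw") {
      lapply(membership, function(acc) intersect(acc, tgw_set))
    } else membership
    memb_t <- memb_t[vapply(memb_t, length, 1L) > 0L]
    rec <- .assemble_records(memb_t, t, sc$mu, bv[[t]], year_eff, year_sds,
                             config$outlier_rate, config$outlier_shift)
    tables[[t]] <- rec$table
    flags[[t]] <- rec$outlier_flags
    year_effects_all[[t]] <- year_eff
    year_sds_all[[t]] <- year_sds
  }
  # implied population partial-regression coefficients of lysine on
  # protein and TGW, from the genetic covariance structure
  sds <- vapply(bv, stats::sd, 1)
  S <- diag(sds) %*% Sigma %*% diag(sds)
  dimnames(S) <- dimnames(Sigma)
  b <- solve(S[c("protein", "tgw"), c("protein", "tgw")],
             S[c("protein", "tgw"), "lysine"])
  rho <- config$altitude_coupling
  lys_std <- as.numeric(scale(bv[["lysine"]]))
  altitude <- setNames(
    round(1200 + 600 * (rho * lys_std + sqrt(1 - rho^2) * rnorm(n))),
    rownames(genotypes))
  truth <- structure(list(
    true_breeding_values = bv,
    marker_effects = effects,
    marker_center = center,
    year_effects = year_effects_all,
    sigma_e2_by_year = lapply(year_sds_all, function(s) s^2),
    outlier_flags = flags,
    adjustment_coefficients = c(b_protein = unname(b["protein"]),
                                b_tgw = unname(b["tgw"])),
    altitude = altitude,
    tgw_accessions = tgw_set
  ), class = "synthetic_truth")
  list(phenotypes = tables, truth = truth)
}
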