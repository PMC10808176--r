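#' Trim unbalanced multi-year records to a connected, replicated core
#'
#' Applies the two curation rules for historical multi-year data
#' iteratively until a fixed point: (1) drop every year whose accession set
#' shares no accession with any other retained year; (2) drop accessions
#' left with a single record (unreplicated data cannot support a reliable
#' adjusted entry mean). Rule order within a pass is years first, then
#' accessions.
#'
#' @param table Long-format phenotype tibble with columns
#'   `accession_id, year, trait, value` (single trait).
#' @return A list with `phenotypes` (the trimmed tibble) and `report`
#'   (class `curation_report`: counts of removed records, accessions and
#'   years, and the mean number of records per retained accession).
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   accession_id = c("a", "a", "b", "b", "c"),
#'   year = c("1970", "1972", "1970", "1972", "1970"),
#'   trait = "protein", value = c(15, 16, 17, 18, 19))
#' trim_records(tab)$report
trim_records <- function(table) {
  tab <- check_phenotypes(table)
  n_in <- nrow(tab)
  years_removed <- character(0)
  acc_removed <- character(0)
  repeat {
    changed <- FALSE
    yrs <- unique(tab$year)
    if (length(yrs) > 1L) {
      by_year <- split(tab$accession_id, tab$year)
      drop_years <- names(by_year)[vapply(names(by_year), function(j) {
        others <- unique(unlist(by_year[setdiff(names(by_year), j)]))
        !any(by_year[[j]] %in% others)
      }, logical(1))]
      if (length(drop_years) > 0L) {
        years_removed <- c(years_removed, drop_years)
        tab <- tab %>% filter(!.data$year %in% drop_years)
        changed <- TRUE
      }
    }
    if (nrow(tab) > 0L) {
      singles <- tab %>% count(.data$accession_id) %>%
        filter(n < 2L) %>% pull(.data$accession_id)
      if (length(singles) > 0L) {
        acc_removed <- c(acc_removed, singles)
        tab <- tab %>% filter(!.data$accession_id %in% singles)
        changed <- TRUE
      }
    }
    if (!changed || nrow(tab) == 0L) break
  }
  if (nrow(tab) == 0L) {
    stop_bad_arg("no connected replicated data remains after trimming",
                 class = "genebankgp_trim_error")
  }
  report <- structure(list(
    n_records_in = n_in,
    n_single_datapoint_accessions_removed = length(unique(acc_removed)),
    years_removed_for_no_overlap = unique(years_removed),
    n_records_out = nrow(tab),
    mean_records_per_accession = nrow(tab) / dplyr::n_distinct(tab$accession_id)
  ), class = "curation_report")
  list(phenotypes = tab, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  records: %d in -> %d out\n", x$n_records_in, x$n_records_out))
  cat(sprintf("  single-datapoint accessions removed: %d\n",
              x$n_single_datapoint_accessions_removed))
  cat(sprintf("  years removed for lacking overlap: %s\n",
              if (length(x$years_removed_for_no_overlap))
                paste(x$years_removed_for_no_overlap, collapse = ", ") else "none"))
  cat(sprintf("  mean records per accession: %.3f\n",
              x$mean_records_per_accession))
  invisible(x)
}

#' Fit the genotype + year mixed model with year-specific error variances
#'
#' Fits `value = mu + g_i + a_j + e_ij` by REML where the year effects
#' `a_j` are random and the residual variance is specific to each year.
#' In `"fixed"` mode the genotype effects are fixed (this is the fit that
#' yields BLUEs, the adjusted entry means); in `"random"` mode genotypes
#' are random with variance `sigma_g2` (the fit used for heritability).
#'
#' @param table Trimmed, connected phenotype tibble (single trait).
#' @param genotype_mode `"fixed"` or `"random"`.
#' @param tol,max_iter REML convergence tolerance on the restricted
#'   log-likelihood and iteration cap.
#' @return Object of class `year_model_fit` with elements `mu`,
#'   `genotype_effects`, `year_effects`, `sigma_g2` (random mode),
#'   `sigma_a2` (year variance), `sigma_e2_by_year`, `sigma_e2_bar`,
#'   `restricted_log_likelihood`, `converged`, per-accession `blues`/`se`
#'   (fixed mode), and record-level `residuals`.
#' @export
fit_year_model <- function(table, genotype_mode = c("fixed", "random"),
                           tol = 1e-8, max_iter = 2000L) {
  genotype_mode <- match.arg(genotype_mode)
  tab <- check_phenotypes(table)
  if (dplyr::n_distinct(tab$year) < 2L) {
    stop_bad_arg("need records from at least two years; trim_records() would have rejected this table")
  }
  acc <- factor(tab$accession_id)
  yr <- factor(tab$year)
  y <- tab$value
  n <- length(y)
  Zacc <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(acc), x = 1,
                               dims = c(n, nlevels(acc)))
  Zyr <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(yr), x = 1,
                              dims = c(n, nlevels(yr)))
  if (genotype_mode == "fixed") {
    # cell-means coding: the fixed-effect solutions ARE the BLUEs mu + g_i
    res <- reml_year_model(y, Zacc, list(Zyr), as.integer(yr), nlevels(yr),
                           tol = tol, max_iter = max_iter)
    blues <- setNames(res$sol[seq_len(res$p)], levels(acc))
    se <- setNames(sqrt(pmax(diag(res$Cinv)[seq_len(res$p)], 0)), levels(acc))
    year_eff <- setNames(res$sol[res$ranef_idx[[1]]], levels(yr))
    mu <- mean(blues)
    genotype_effects <- blues - mu
    sigma_a2 <- res$sigma_r2[1]
    sigma_g2 <- NA_real_
  } else {
    X <- Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                              dims = c(n, 1L))
    res <- reml_year_model(y, X, list(Zacc, Zyr), as.integer(yr), nlevels(yr),
                           tol = tol, max_iter = max_iter)
    mu <- res$sol[1]
    genotype_effects <- setNames(res$sol[res$ranef_idx[[1]]], levels(acc))
    year_eff <- setNames(res$sol[res$ranef_idx[[2]]], levels(yr))
    sigma_g2 <- res$sigma_r2[1]
    sigma_a2 <- res$sigma_r2[2]
    blues <- NULL
    se <- NULL
  }
  sigma_e2_by_year <- setNames(res$sigma_j2, levels(yr))
  residuals <- tab %>%
    mutate(fitted = .data$value - res$ehat,
           residual = res$ehat,
           residual_sd = sqrt(sigma_e2_by_year[as.character(.data$year)]))
  structure(list(
    mode = genotype_mode,
    trait = tab$trait[1],
    mu = mu,
    genotype_effects = genotype_effects,
    year_effects = year_eff,
    blues = blues,
    se = se,
    sigma_g2 = sigma_g2,
    sigma_a2 = sigma_a2,
    sigma_e2_by_year = sigma_e2_by_year,
    sigma_e2_bar = mean(sigma_e2_by_year),
    restricted_log_likelihood = res$loglik,
    loglik_trace = res$ll_trace,
    converged = res$converged,
    n_iter = res$n_iter,
    n_records = n,
    boundary_years = levels(yr)[res$boundary_years],
    residuals = residuals
  ), class = "year_model_fit")
}

#' @export
print.year_model_fit <- function(x, ...) {
  cat(sprintf("Year mixed model (%s genotypes), trait %s\n", x$mode, x$trait))
  cat(sprintf("  %d records, %d accessions, %d years\n", x$n_records,
              length(x$genotype_effects), length(x$year_effects)))
  if (x$mode == "random") cat(sprintf("  sigma_g2 = %.4g\n", x$sigma_g2))
  cat(sprintf("  sigma_a2 (year) = %.4g, mean sigma_e2 = %.4g\n",
              x$sigma_a2, x$sigma_e2_bar))
  cat(sprintf("  restricted logLik %.4f (%s, %d iterations)\n",
              x$restricted_log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Detect phenotypic outliers from standardized residuals
#'
#' Standardizes each record's residual by its year-specific residual SD,
#' computes two-sided standard-normal p-values and applies Holm's step-down
#' familywise correction at `alpha`.
#'
#' @param table The phenotype tibble the model was fitted on.
#' @param fit A converged [fit_year_model()] (fixed mode) on `table`.
#' @param alpha Familywise significance level.
#' @return Integer row indices of `table` flagged as outliers, sorted by
#'   decreasing absolute standardized residual.
#' @export
detect_outliers <- function(table, fit, alpha = 0.05) {
  stopifnot(inherits(fit, "year_model_fit"))
  check_number(alpha, "alpha", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  if (!fit$converged) {
    stop_bad_arg("refusing to screen outliers with a non-converged model fit")
  }
  if (nrow(fit$residuals) != nrow(table)) {
    stop_bad_arg("`fit` was not fitted on `table` (record count differs)")
  }
  if (length(fit$boundary_years) > 0L) {
    stop_bad_arg(sprintf(
      "residual variance is at the zero boundary in year(s) %s; records of these years cannot be tested (too few multi-record accessions identify the year-specific variance)",
      paste(fit$boundary_years, collapse = ", ")))
  }
  sds <- fit$residuals$residual_sd
  z <- unname(fit$residuals$residual / sds)
  p <- 2 * pnorm(-abs(z))
  flagged <- which(p.adjust(p, method = "holm") <= alpha)
  flagged[order(abs(z[flagged]), decreasing = TRUE)]
}

#' Entry-mean and plot-based heritability from variance components
#'
#' Closed forms: `h2 = sigma_g2 / (sigma_g2 + sigma_e2_bar / n_bar)` (the
#' precision of genotype means tested in `n_bar` years on average) and
#' `h2_pb = sigma_g2 / (sigma_g2 + sigma_e2_bar)` (a single plot).
#'
#' @param sigma_g2 Genetic variance.
#' @param sigma_e2_bar Mean of the year-specific residual variances.
#' @param n_bar Average number of years in which an accession was tested.
#' @return Object of class `heritability_stats` with `h2`, `h2_pb` and the
#'   inputs.
#' @export
#' @examples
#' estimate_heritability(4.017, 2.679, 2.407)  # h2 = 0.78, h2_pb = 0.60
estimate_heritability <- function(sigma_g2, sigma_e2_bar, n_bar) {
  check_number(sigma_g2, "sigma_g2", 0)
  check_number(sigma_e2_bar, "sigma_e2_bar", 0)
  check_number(n_bar, "n_bar", 1)
  if (sigma_g2 == 0 && sigma_e2_bar == 0) {
    stop_bad_arg("heritability is undefined when both variance components are zero")
  }
  structure(list(
    h2 = sigma_g2 / (sigma_g2 + sigma_e2_bar / n_bar),
    h2_pb = sigma_g2 / (sigma_g2 + sigma_e2_bar),
    sigma_g2 = sigma_g2,
    sigma_e2_bar = sigma_e2_bar,
    n_bar = n_bar
  ), class = "heritability_stats")
}

#' @export
print.heritability_stats <- function(x, ...) {
  cat(sprintf("h2 = %.3f (entry-mean), h2_pb = %.3f (plot-based)\n",
              x$h2, x$h2_pb))
  cat(sprintf("  sigma_g2 = %.4g, mean sigma_e2 = %.4g, mean years tested = %.3f\n",
              x$sigma_g2, x$sigma_e2_bar, x$n_bar))
  invisible(x)
}

.nbar <- function(tab) {
  nrow(tab) / dplyr::n_distinct(tab$accession_id)
}

#' Outlier-corrected BLUEs with before/after heritabilities
#'
#' The full curation loop for one trait: trim the records, then repeat
#' (fit the fixed-genotype model, flag outliers via [detect_outliers()],
#' drop them, re-trim) until no record is flagged (at most `max_rounds`
#' rounds). Heritabilities come from the random-genotype fit before the
#' first removal and after the last one; the BLUEs come from the final
#' fixed-genotype fit.
#'
#' @param table Raw long-format phenotype tibble (single trait).
#' @param alpha Familywise level for outlier flagging.
#' @param max_rounds Cap on correction rounds.
#' @return Object of class `blues_fit` with `blues` (tibble
#'   `accession_id, trait, blue, se, n_years`), `h2_before`, `h2_after`
#'   ([estimate_heritability()] objects), `outliers_removed`,
#'   `removed_records`, `curation` (final [trim_records()] report) and the
#'   final fixed-mode `fit`.
#' @export
compute_blues <- function(table, alpha = 0.05, max_rounds = 10L) {
  trimmed <- trim_records(table)
  tab <- trimmed$phenotypes
  fit_rand_before <- fit_year_model(tab, "random")
  h2_before <- estimate_heritability(fit_rand_before$sigma_g2,
                                     fit_rand_before$sigma_e2_bar,
                                     .nbar(tab))
  removed <- tab[0, ]
  rounds <- 0L
  repeat {
    fit_fixed <- fit_year_model(tab, "fixed")
    flags <- detect_outliers(tab, fit_fixed, alpha = alpha)
    if (length(flags) == 0L) break
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      stop_bad_arg(sprintf(
        "outlier correction did not stabilize within %d rounds (%d records still flagged)",
        max_rounds, length(flags)))
    }
    removed <- dplyr::bind_rows(removed, tab[flags, ])
    tab <- tab[-flags, ]
    tab <- trim_records(tab)$phenotypes
  }
  fit_rand_after <- fit_year_model(tab, "random")
  h2_after <- estimate_heritability(fit_rand_after$sigma_g2,
                                    fit_rand_after$sigma_e2_bar,
                                    .nbar(tab))
  n_years <- tab %>% count(.data$accession_id, name = "n_years")
  blues <- tibble(accession_id = names(fit_fixed$blues),
                  trait = tab$trait[1],
                  blue = unname(fit_fixed$blues),
                  se = unname(fit_fixed$se)) %>%
    left_join(n_years, by = "accession_id")
  structure(list(
    blues = blues,
    h2_before = h2_before,
    h2_after = h2_after,
    outliers_removed = nrow(removed),
    removed_records = removed,
    curation = trimmed$report,
    correction_rounds = rounds,
    fit = fit_fixed,
    fit_random = fit_rand_after,
    phenotypes = tab
  ), class = "blues_fit")
}

#' @export
print.blues_fit <- function(x, ...) {
  cat(sprintf("BLUEs for %s: %d accessions, %d outlier records removed in %d round(s)\n",
              x$blues$trait[1], nrow(x$blues), x$outliers_removed,
              x$correction_rounds))
  cat(sprintf("  h2 before %.3f -> after %.3f; h2_pb before %.3f -> after %.3f\n",
              x$h2_before$h2, x$h2_after$h2, x$h2_before$h2_pb, x$h2_after$h2_pb))
  invisible(x)
}
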