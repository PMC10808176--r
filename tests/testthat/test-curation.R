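make_tab <- function(acc, year, value = seq_along(acc), trait = "protein") {
  tibble::tibble(accession_id = acc, year = year, trait = trait,
                 value = as.numeric(value))
}

test_that("trimming removes disconnected years and unreplicated accessions to a fixed point", {
  # fully replicated data passes untouched
  tab <- make_tab(rep(c("a", "b", "c"), each = 2), rep(c("Y1", "Y2"), 3))
  out <- trim_records(tab)
  expect_identical(out$phenotypes, tab)
  expect_identical(out$report$n_single_datapoint_accessions_removed, 0L)
  expect_identical(out$report$years_removed_for_no_overlap, character(0))

  # a year whose six records belong to accessions seen nowhere else is dropped
  tab2 <- dplyr::bind_rows(tab, make_tab(paste0("x", 1:6), "Y1983"))
  out2 <- trim_records(tab2)
  expect_identical(out2$report$years_removed_for_no_overlap, "Y1983")
  expect_false("Y1983" %in% out2$phenotypes$year)
  expect_identical(nrow(out2$phenotypes), 6L)

  # a single-record accession among replicated data is removed
  tab3 <- dplyr::bind_rows(tab, make_tab("lonely", "Y1"))
  out3 <- trim_records(tab3)
  expect_false("lonely" %in% out3$phenotypes$accession_id)
  expect_identical(out3$report$n_single_datapoint_accessions_removed, 1L)

  # cascade: dropping a disconnected year leaves an accession unreplicated,
  # which the next pass removes (fixed-point iteration)
  tab4 <- dplyr::bind_rows(
    tab,
    make_tab(c("d", "d"), c("Y1", "Y3")),
    make_tab("e", "Y3"))
  # Y3 holds d and e only; d also in Y1 so Y3 overlaps; e is single -> e out,
  # then d keeps 2 records -> stable
  out4 <- trim_records(tab4)
  expect_false("e" %in% out4$phenotypes$accession_id)
  expect_true(all(c("d") %in% out4$phenotypes$accession_id))
  expect_gte(out4$report$mean_records_per_accession, 2)

  # nothing connected and replicated -> explicit error
  expect_error(trim_records(make_tab(c("a", "b"), c("Y1", "Y2"))),
               class = "genebankgp_trim_error")

  # duplicated (accession, year, trait) rows are a hard error
  expect_error(trim_records(make_tab(c("a", "a"), c("Y1", "Y1"))),
               "duplicated")
})

test_that("the year mixed model reproduces closed-form GLS on a balanced toy", {
  tab <- balanced_toy(noise_sd = 0)
  fit <- fit_year_model(tab, "fixed")
  # genotype differences are estimated exactly on balanced no-noise data
  expect_equal(unname(fit$blues["g2"] - fit$blues["g1"]), 1, tolerance = 1e-6)
  expect_equal(unname(fit$blues["g3"] - fit$blues["g1"]), 2, tolerance = 1e-6)
  # year effect direction recovered
  expect_gt(fit$year_effects["Y1"], fit$year_effects["Y2"])

  # with noise, the fit agrees with a dense GLS oracle evaluated at the
  # fitted variance components
  tab2 <- balanced_toy(noise_sd = 0.3, seed = 4)
  extra <- balanced_toy(noise_sd = 0.3, seed = 5)
  extra$year <- paste0(extra$year, "b")
  tab2 <- dplyr::bind_rows(tab2, extra)
  fit2 <- fit_year_model(tab2, "fixed")
  acc <- factor(tab2$accession_id); yr <- factor(tab2$year)
  X <- stats::model.matrix(~ 0 + acc)
  Z <- stats::model.matrix(~ 0 + yr)
  V <- fit2$sigma_a2 * tcrossprod(Z) +
    diag(fit2$sigma_e2_by_year[as.integer(yr)])
  b <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, tab2$value)))
  expect_equal(unname(fit2$blues), unname(drop(b)), tolerance = 1e-6)

  expect_error(fit_year_model(make_tab(c("a", "b"), c("Y1", "Y1"))),
               "two years")
})

test_that("REML matches an independent mixed-model implementation on unbalanced data", {
  cfg <- sim_config(n_accessions = 60, n_markers = 200, outlier_rate = 0,
                    seed = 3)
  sim <- simulate_trial(simulate_genotypes(cfg), cfg, trait = "p", mu = 10)
  tab <- trim_records(sim$phenotypes)$phenotypes
  fit <- fit_year_model(tab, "fixed")
  # interior optimum: all year variances well identified here
  expect_length(fit$boundary_years, 0L)
  fr <- fit_year_model(tab, "random")

  d <- as.data.frame(tab)
  d$accession_id <- factor(d$accession_id)
  d$year <- factor(d$year)
  tm <- glmmTMB::glmmTMB(value ~ 0 + accession_id + (1 | year),
                         dispformula = ~ 0 + year, data = d, REML = TRUE)
  expect_equal(unname(fit$blues), unname(glmmTMB::fixef(tm)$cond),
               tolerance = 1e-3)
  expect_equal(unname(fit$sigma_e2_by_year),
               unname(exp(glmmTMB::fixef(tm)$disp)^2), tolerance = 1e-3)
  expect_equal(fit$sigma_a2,
               unname(glmmTMB::VarCorr(tm)$cond$year[1, 1]), tolerance = 1e-3)

  tr <- glmmTMB::glmmTMB(value ~ 1 + (1 | accession_id) + (1 | year),
                         dispformula = ~ 0 + year, data = d, REML = TRUE)
  expect_equal(fr$sigma_g2,
               unname(glmmTMB::VarCorr(tr)$cond$accession_id[1, 1]),
               tolerance = 1e-3)
  expect_equal(fr$mu, unname(glmmTMB::fixef(tr)$cond[1]), tolerance = 1e-4)

  # restricted log-likelihood is monotone along the EM trace
  expect_true(all(diff(fr$loglik_trace) > -1e-6))
})

test_that("REML recovers the generating variance components on simulated trials", {
  rel_err <- function(est, truth) abs(est - truth) / truth
  errs <- sapply(1:10, function(s) {
    cfg <- sim_config(n_accessions = 400, n_markers = 60, outlier_rate = 0,
                      seed = 100 + s)
    sim <- simulate_trial(simulate_genotypes(cfg), cfg, mu = 8)
    tab <- trim_records(sim$phenotypes)$phenotypes
    fr <- fit_year_model(tab, "random")
    c(g = rel_err(fr$sigma_g2, sim$truth$sigma_g2),
      e = rel_err(fr$sigma_e2_bar, mean(sim$truth$sigma_e2_by_year)))
  })
  expect_lt(mean(errs["g", ]), 0.2)
  expect_lt(mean(errs["e", ]), 0.2)
})

test_that("outlier flags equal the brute-force Holm oracle and catch gross outliers", {
  cfg <- sim_config(n_accessions = 80, n_markers = 50, outlier_rate = 0,
                    seed = 17)
  sim <- simulate_trial(simulate_genotypes(cfg), cfg, mu = 10)
  tab <- trim_records(sim$phenotypes)$phenotypes
  fit <- fit_year_model(tab, "fixed")

  z <- fit$residuals$residual / fit$residuals$residual_sd
  p <- 2 * pnorm(-abs(z))
  for (alpha in c(0.01, 0.05, 0.2, 0.8)) {
    expect_setequal(detect_outliers(tab, fit, alpha), holm_oracle(p, alpha))
  }
  # flags come sorted by decreasing |standardized residual|
  fl <- detect_outliers(tab, fit, 0.9)
  expect_false(is.unsorted(rev(abs(z[fl]))))

  # a 10-SD contaminated record is flagged exactly
  tab2 <- tab
  idx <- 25L
  tab2$value[idx] <- tab2$value[idx] +
    10 * sqrt(fit$sigma_e2_by_year[tab2$year[idx]])
  fit2 <- fit_year_model(tab2, "fixed")
  expect_identical(detect_outliers(tab2, fit2, 0.05), idx)
})

test_that("familywise error control keeps false outlier flags rare on clean data", {
  n_flags <- sapply(1:40, function(s) {
    cfg <- sim_config(n_accessions = 80, n_markers = 40, outlier_rate = 0,
                      seed = 500 + s)
    sim <- simulate_trial(simulate_genotypes(cfg), cfg, mu = 10)
    tab <- trim_records(sim$phenotypes)$phenotypes
    length(detect_outliers(tab, fit_year_model(tab, "fixed"), 0.05))
  })
  expect_lt(mean(n_flags), 0.2)
})

test_that("the BLUE loop removes planted outliers and improves heritability", {
  cfg <- sim_config(n_accessions = 250, n_markers = 80, outlier_rate = 0,
                    seed = 23)
  sim <- simulate_trial(simulate_genotypes(cfg), cfg, mu = 12)
  tab <- trim_records(sim$phenotypes)$phenotypes
  # plant 8 gross outliers (8 residual SDs, random sign)
  set.seed(99)
  planted <- sample(nrow(tab), 8)
  shift <- 8 * sqrt(sim$truth$sigma_e2_by_year[tab$year[planted]])
  tab$value[planted] <- tab$value[planted] +
    shift * sample(c(-1, 1), 8, replace = TRUE)
  key <- paste(tab$accession_id[planted], tab$year[planted])

  res <- compute_blues(tab)
  removed_key <- paste(res$removed_records$accession_id,
                       res$removed_records$year)
  expect_gte(sum(key %in% removed_key), 6)
  expect_gte(res$h2_after$h2, res$h2_before$h2)
  expect_gte(res$h2_after$h2_pb, res$h2_before$h2_pb)
  # removing gross outliers lowers the mean residual variance
  expect_lt(res$h2_after$sigma_e2_bar, res$h2_before$sigma_e2_bar)

  # outlier-free input: zero removals, before == after
  res0 <- compute_blues(trim_records(sim$phenotypes)$phenotypes)
  expect_identical(res0$outliers_removed, 0L)
  expect_equal(res0$h2_before$h2, res0$h2_after$h2, tolerance = 1e-10)

  # BLUEs track the simulated breeding values
  expect_gt(cor(res0$blues$blue,
                (12 + sim$truth$true_breeding_values)[res0$blues$accession_id]),
            0.7)
})

test_that("heritability closed forms, boundaries and monotonicity behave", {
  h <- estimate_heritability(4.017, 2.679, 2.407)
  expect_equal(round(h$h2, 2), 0.78)
  expect_equal(round(h$h2_pb, 2), 0.60)

  expect_equal(estimate_heritability(1, 0, 2)$h2, 1)
  expect_equal(estimate_heritability(0, 1, 2)$h2, 0)
  expect_error(estimate_heritability(0, 0, 2), "undefined")
  expect_error(estimate_heritability(-1, 1, 2),
               class = "genebankgp_config_error")
  expect_error(estimate_heritability(1, 1, 0.5),
               class = "genebankgp_config_error")

  # h2 increases in n_bar and sigma_g2; plot-based never exceeds entry-mean
  hs <- sapply(c(1, 2, 5, 10), function(nb)
    estimate_heritability(1, 1, nb)$h2)
  expect_false(is.unsorted(hs))
  gs <- sapply(c(0.1, 0.5, 1, 3), function(g)
    estimate_heritability(g, 1, 2)$h2)
  expect_false(is.unsorted(gs))
  for (nb in c(1, 2.4, 7)) {
    st <- estimate_heritability(0.7, 1.3, nb)
    expect_lte(st$h2_pb, st$h2)
  }
})
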