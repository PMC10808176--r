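test_that("fold plans are balanced partitions, reproducible under seed", {
  f <- make_folds(sprintf("a%02d", 1:10), k = 5, repeats = 2, seed = 1)
  sizes <- dplyr::count(f, repeat_index, fold)$n
  expect_true(all(sizes == 2L))

  # at the study's training-set size the folds split 67/67/67/68/68
  ids <- sprintf("w%03d", 1:337)
  f2 <- make_folds(ids, k = 5, repeats = 3, seed = 2)
  for (r in 1:3) {
    fr <- f2[f2$repeat_index == r, ]
    expect_setequal(fr$accession_id, ids)          # union = all
    expect_identical(anyDuplicated(fr$accession_id), 0L)  # disjoint
    expect_setequal(unique(dplyr::count(fr, fold)$n), c(67L, 68L))
  }

  # deterministic rerun, repeats mutually different
  f3 <- make_folds(ids, k = 5, repeats = 3, seed = 2)
  expect_identical(f2, f3)
  a1 <- f2$fold[f2$repeat_index == 1][order(f2$accession_id[f2$repeat_index == 1])]
  a2 <- f2$fold[f2$repeat_index == 2][order(f2$accession_id[f2$repeat_index == 2])]
  expect_false(identical(a1, a2))

  expect_error(make_folds(c("a", "b"), k = 5), "exceeds")
})

test_that("prediction ability is 1 for an oracle, -1 for an anti-oracle, ~0 for the mean", {
  set.seed(3)
  n <- 300
  ids <- sprintf("a%03d", 1:n)
  blues <- tibble::tibble(accession_id = ids, trait = "t",
                          blue = rnorm(n, 10, 2))
  ytrue <- setNames(blues$blue, ids)
  oracle <- function(train, test_ids) ytrue[test_ids]
  anti <- function(train, test_ids) -ytrue[test_ids]
  mean_model <- function(train, test_ids) {
    setNames(rep(mean(train$blue), length(test_ids)), test_ids)
  }
  folds <- make_folds(ids, k = 5, repeats = 10, seed = 4)
  cv <- cross_validate(blues, list(oracle = oracle, anti = anti,
                                   mean = mean_model), folds)
  s <- glance(cv)
  expect_equal(s$mean_ability[s$model == "oracle"], 1, tolerance = 1e-12)
  expect_equal(s$mean_ability[s$model == "anti"], -1, tolerance = 1e-12)
  # the training-mean model shows the well-known small negative k-fold
  # artifact (test-fold values high exactly when the training mean is low),
  # of order -1/sqrt(fold size); "approximately zero" means within 0.15 here
  expect_lt(abs(s$mean_ability[s$model == "mean"]), 0.15)
  expect_true(all(cv$ability >= -1 & cv$ability <= 1, na.rm = TRUE))

  # constant predictions yield an undefined ability, recorded as NA
  const <- function(train, test_ids) setNames(rep(1, length(test_ids)), test_ids)
  cvc <- suppressMessages(
    cross_validate(blues, list(const = const),
                   make_folds(ids, k = 5, repeats = 2, seed = 5)))
  expect_true(all(is.na(cvc$ability)))
  expect_identical(glance(cvc)$n_undefined, 2L)
})

test_that("genomic cross-validation is self-consistent across independent batches", {
  geno <- quick_geno(300, 500, seed = 6)
  ph <- blue_phenotypes(geno, h2 = 0.5, seed = 7)
  G <- compute_grm(geno)
  run_batch <- function(seed) {
    folds <- make_folds(rownames(geno), k = 5, repeats = 8, seed = seed)
    glance(cross_validate(ph$blues, list(gblup = "gblup"), folds,
                          G = G))$mean_ability
  }
  b1 <- run_batch(11)
  b2 <- run_batch(12)
  expect_lt(abs(b1 - b2), 0.03)
  # abilities land in the plausible range for h2 = 0.5 with causal markers
  expect_gt(b1, 0.3)
  expect_lt(b1, 0.9)
})

test_that("derived-trait strategies coincide when the coupling is exactly linear", {
  geno <- quick_geno(200, 300, seed = 8)
  Zc <- sweep(geno, 2L, colMeans(geno))
  set.seed(9)
  g_p <- drop(Zc %*% rnorm(300)); g_p <- g_p / sd(g_p)
  g_t <- drop(Zc %*% rnorm(300)); g_t <- g_t / sd(g_t)
  g_r <- drop(Zc %*% rnorm(300)); g_r <- g_r / sd(g_r)  # genetic residual
  ids <- rownames(geno)
  mk <- function(v, tr) tibble::tibble(accession_id = ids, trait = tr, blue = v)
  protein <- mk(17 + 2 * g_p + rnorm(200, 0, 0.5), "protein")
  tgw <- mk(45 + 5 * g_t + rnorm(200, 0, 1), "tgw")
  lysine <- mk(2 + 0.1 * protein$blue - 0.05 * tgw$blue + 0.3 * g_r, "lysine")
  adj_model <- fit_adjustment(lysine, protein, tgw)
  adjusted <- adjust_lysine(lysine, protein, tgw, adj_model)
  G <- compute_grm(geno)
  folds <- make_folds(ids, k = 5, repeats = 3, seed = 10)
  cmp <- compare_derived_strategies(lysine, protein, tgw, adjusted, folds,
                                    model = "gblup", G = G)
  expect_lt(abs(mean(cmp$difference)), 0.02)
  expect_identical(nrow(cmp), 3L)
  expect_equal(cmp$difference,
               cmp$ability_direct - cmp$ability_component, tolerance = 1e-12)
})

test_that("whole-collection prediction splits summaries by training membership", {
  geno <- quick_geno(150, 300, seed = 13)
  ph <- blue_phenotypes(geno, h2 = 0.8, seed = 14)
  G <- compute_grm(geno)
  H <- compute_epistatic(G)

  # everyone in training: fitted values track the BLUEs closely at high h2
  pc <- predict_collection(ph$blues, "egblup", G = G, H = H)
  expect_identical(nrow(pc$predictions), 150L)
  expect_true(all(pc$predictions$in_training))
  expect_identical(nrow(pc$summary), 1L)  # degenerate split handled
  m <- merge(pc$predictions, ph$blues, by = "accession_id")
  expect_gt(cor(m$predicted_value, m$blue), 0.9)

  # genotyped-only accessions related to low-value training families are
  # predicted below the training mean
  ord <- order(ph$g)
  low_related <- rownames(geno)[ord[seq_len(40)]]
  train <- ph$blues[!ph$blues$accession_id %in% low_related, ]
  pc2 <- predict_collection(train, "gblup", G = G)
  s <- pc2$summary
  expect_identical(nrow(s), 2L)
  expect_lt(s$mean[!s$in_training], s$mean[s$in_training])
})

test_that("culling-level selection thresholds behave like normal quantiles", {
  set.seed(15)
  n <- 10000
  ids <- sprintf("c%05d", 1:n)
  two_traits <- function(x, y) {
    dplyr::bind_rows(
      tibble::tibble(accession_id = ids, trait = "protein",
                     predicted_value = x),
      tibble::tibble(accession_id = ids, trait = "lysine_adjusted",
                     predicted_value = y))
  }
  indep <- two_traits(rnorm(n), rnorm(n))
  sel999 <- culling_select(indep, 0.999)
  sel99 <- culling_select(indep, 0.99)
  # independent traits: expected counts n * (1 - level)^2
  expect_lte(length(sel999$selected), 3)
  expect_lte(length(sel99$selected), 10)
  expect_true(all(sel999$selected %in% sel99$selected))
  # thresholds strictly increase with the selection level
  expect_true(all(sel999$thresholds > sel99$thresholds))

  # perfectly correlated traits reduce to single-trait selection (~1%)
  z <- rnorm(n)
  corr <- two_traits(z, z)
  sel <- culling_select(corr, 0.99)
  expect_equal(length(sel$selected) / n, 0.01, tolerance = 0.35)

  # empirical mode matches the order statistics
  sel_emp <- culling_select(corr, 0.99, mode = "empirical")
  expect_equal(length(sel_emp$selected) / n, 0.01, tolerance = 0.05)

  # monotone nesting on arbitrary (correlated, skewed) inputs
  skew <- two_traits(exp(rnorm(n)), z + 0.5 * rnorm(n))
  s1 <- culling_select(skew, 0.99)
  s2 <- culling_select(skew, 0.999)
  expect_true(all(s2$selected %in% s1$selected))

  flat <- two_traits(rep(1, n), rnorm(n))
  expect_error(culling_select(flat, 0.99), "zero spread")
  expect_error(culling_select(indep, 0.4), class = "genebankgp_config_error")
  expect_error(culling_select(indep[indep$trait == "protein", ], 0.99),
               "exactly 2")
})

test_that("altitude associations recover the generator coupling and edge cases", {
  cfg <- sim_config(n_accessions = 500, n_markers = 300, seed = 16)
  geno <- simulate_genotypes(cfg)
  ct <- simulate_correlated_traits(geno, cfg)
  bv <- ct$truth$true_breeding_values
  passport <- tibble::tibble(accession_id = names(ct$truth$altitude),
                             altitude = as.numeric(ct$truth$altitude))
  preds <- tibble::tibble(accession_id = names(bv$lysine), trait = "lysine",
                          predicted_value = unname(bv$lysine))
  out <- altitude_association(preds, passport)
  expect_identical(out$n, 500L)
  expect_lt(abs(out$r - cfg$altitude_coupling), 0.15)
  expect_lt(out$p_value, 0.01)

  # identical values give r = 1; constant altitude is an error
  self <- tibble::tibble(accession_id = passport$accession_id,
                         trait = "alt", predicted_value = passport$altitude)
  expect_equal(altitude_association(self, passport)$r, 1, tolerance = 1e-12)
  flat <- passport
  flat$altitude <- 1000
  expect_error(altitude_association(self, flat), "constant")
  expect_error(altitude_association(preds[1:2, ], passport[1:2, ]),
               "fewer than 3")
})
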