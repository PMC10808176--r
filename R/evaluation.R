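#' Balanced fold assignments for replicated k-fold cross-validation
#'
#' Per repeat, accessions are shuffled and split into `k` folds whose sizes
#' differ by at most one (the remainder spread over the first folds after
#' shuffling). Repeats are mutually independent and the whole plan is
#' deterministic given `seed`.
#'
#' @param accessions Character vector of accession labels.
#' @param k Number of folds.
#' @param repeats Number of independent repeats.
#' @param seed Integer seed.
#' @return Tibble `repeat_index, accession_id, fold`.
#' @export
make_folds <- function(accessions, k = 5L, repeats = 100L, seed = 1L) {
  accessions <- as.character(accessions)
  n <- length(accessions)
  k <- check_count(k, "k", min = 2L)
  repeats <- check_count(repeats, "repeats")
  if (k > n) stop_bad_arg(sprintf("k = %d exceeds the %d accessions", k, n))
  if (anyDuplicated(accessions)) stop_bad_arg("duplicated accession labels")
  set.seed(seed)
  purrr::map_dfr(seq_len(repeats), function(r) {
    shuffled <- sample(accessions)
    sizes <- rep(n %/% k, k)
    rem <- n %% k
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    tibble(repeat_index = r, accession_id = shuffled,
           fold = rep(seq_len(k), times = sizes))
  })
}

# dispatch a model label / spec / function to a fitted object or, for a
# function, directly to predictions of the test accessions
.fit_and_predict <- function(model, train_blues, test_ids,
                             G = NULL, H = NULL, markers = NULL) {
  if (is.function(model)) {
    pred <- model(train_blues, test_ids)
    return(tibble(accession_id = test_ids,
                  predicted_value = unname(pred[test_ids])))
  }
  fit <- .fit_model(model, train_blues, G = G, H = H, markers = markers)
  predict(fit, test_ids)[, c("accession_id", "predicted_value")]
}

.fit_model <- function(model, blues, G = NULL, H = NULL, markers = NULL) {
  if (inherits(model, "model_spec")) {
    if (is.null(markers)) {
      stop_bad_arg(sprintf("model %s needs the marker matrix", model$model))
    }
    return(switch(model$model,
                  bayes_a = fit_bayes_a(blues, markers, model),
                  bayesian_lasso = fit_bayesian_lasso(blues, markers, model)))
  }
  if (is.character(model) && length(model) == 1L) {
    return(switch(model,
                  gblup = {
                    if (is.null(G)) stop_bad_arg("gblup needs `G`")
                    fit_gblup(blues, G)
                  },
                  egblup = {
                    if (is.null(G) || is.null(H)) {
                      stop_bad_arg("egblup needs `G` and `H`")
                    }
                    fit_egblup(blues, G, H)
                  },
                  bayes_a = fit_bayes_a(blues, markers %||%
                                          stop_bad_arg("bayes_a needs `markers`")),
                  bayesian_lasso = fit_bayesian_lasso(blues, markers %||%
                                                        stop_bad_arg("bayesian_lasso needs `markers`")),
                  stop_bad_arg(sprintf("unknown model '%s'", model))))
  }
  stop_bad_arg("models must be labels ('gblup', 'egblup', 'bayes_a', 'bayesian_lasso'), model_spec objects or functions")
}

.model_label <- function(model, i) {
  if (is.character(model)) model
  else if (inherits(model, "model_spec")) model$model
  else paste0("custom_", i)
}

#' Replicated cross-validated prediction abilities
#'
#' For every repeat of the fold plan, each fold is predicted once from a
#' model trained on the remaining folds; the pooled test-set predictions
#' are correlated with the BLUEs (Pearson), giving one prediction ability
#' per model and repeat. All models see identical training/test splits
#' within a repeat, and variance components are re-estimated inside every
#' training fold.
#'
#' @param blues BLUE table (tibble `accession_id`, `blue`, optionally
#'   `trait`) or a [compute_blues()] result.
#' @param models Named or unnamed list of models: labels `"gblup"` /
#'   `"egblup"` / `"bayes_a"` / `"bayesian_lasso"`, [model_spec()] objects,
#'   or functions `f(train_blues, test_ids)` returning named predictions.
#' @param folds Fold plan from [make_folds()]; every accession in it must
#'   have a BLUE and genomic data.
#' @param G,H,markers Genomic inputs passed to the models that need them.
#' @return Object of class `cv_result`: tibble
#'   `model, trait, repeat_index, ability` with a `summary` attribute
#'   (mean/median/sd ability per model).
#' @export
cross_validate <- function(blues, models, folds, G = NULL, H = NULL,
                           markers = NULL) {
  tab <- .check_blues(blues, "blues")
  trait <- if ("trait" %in% names(tab)) tab$trait[1] else "trait"
  if (!all(c("repeat_index", "accession_id", "fold") %in% names(folds))) {
    stop_bad_arg("`folds` must come from make_folds()")
  }
  missing_blues <- setdiff(folds$accession_id, tab$accession_id)
  if (length(missing_blues) > 0L) {
    stop_bad_arg(sprintf("%d fold accessions lack BLUEs (e.g. %s)",
                         length(missing_blues),
                         paste(head(missing_blues, 3), collapse = ", ")))
  }
  if (!is.list(models)) models <- as.list(models)
  nms <- names(models) %||% rep("", length(models))
  labels <- vapply(seq_along(models), function(i) {
    if (nzchar(nms[i])) nms[i] else .model_label(models[[i]], i)
  }, character(1))
  y_all <- setNames(tab$blue, tab$accession_id)
  res <- purrr::map_dfr(split(folds, folds$repeat_index), function(fp) {
    r <- fp$repeat_index[1]
    purrr::map_dfr(seq_along(models), function(mi) {
      preds <- purrr::map_dfr(sort(unique(fp$fold)), function(f) {
        test_ids <- fp$accession_id[fp$fold == f]
        train_blues <- tab %>% filter(!.data$accession_id %in% test_ids)
        .fit_and_predict(models[[mi]], train_blues, test_ids,
                         G = G, H = H, markers = markers)
      })
      pv <- preds$predicted_value
      ability <- if (stats::sd(pv) < 1e-12) {
        inform(sprintf(
          "repeat %d, model %s: constant predictions; ability undefined",
          r, labels[mi]))
        NA_real_
      } else {
        cor(y_all[preds$accession_id], pv)
      }
      tibble(model = labels[mi], trait = trait, repeat_index = r,
             ability = ability)
    })
  })
  summary <- res %>%
    group_by(.data$model) %>%
    summarise(mean_ability = mean(.data$ability, na.rm = TRUE),
              median_ability = stats::median(.data$ability, na.rm = TRUE),
              sd_ability = stats::sd(.data$ability, na.rm = TRUE),
              n_undefined = sum(is.na(.data$ability)), .groups = "drop")
  structure(res, class = c("cv_result", class(res)), summary = summary)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation: %d repeats, trait %s\n",
              dplyr::n_distinct(x$repeat_index), x$trait[1]))
  print(attr(x, "summary"))
  invisible(x)
}

#' Direct versus component-wise prediction of adjusted lysine
#'
#' Strategy A predicts the derived trait (adjusted lysine) directly;
#' strategy B predicts lysine, protein and TGW separately, refits the
#' adjustment on each training fold (avoiding leakage) and derives the
#' adjusted value from the three predictions. Both strategies are scored
#' against the adjusted-lysine BLUEs on identical folds.
#'
#' @param lysine,protein,tgw,adjusted BLUE tables of the component traits
#'   and of the derived trait.
#' @param folds Fold plan over the accessions of `adjusted`.
#' @param model Model label or [model_spec()] used by both strategies.
#' @inheritParams cross_validate
#' @return Object of class `strategy_comparison`: tibble
#'   `repeat_index, ability_direct, ability_component, difference`.
#' @export
compare_derived_strategies <- function(lysine, protein, tgw, adjusted, folds,
                                       model = "gblup", G = NULL, H = NULL,
                                       markers = NULL) {
  adj <- .check_blues(adjusted, "adjusted")
  lys <- .check_blues(lysine, "lysine")
  pro <- .check_blues(protein, "protein")
  tg <- .check_blues(tgw, "tgw")
  y_adj <- setNames(adj$blue, adj$accession_id)
  folds <- folds %>% filter(.data$accession_id %in% adj$accession_id)
  res <- purrr::map_dfr(split(folds, folds$repeat_index), function(fp) {
    r <- fp$repeat_index[1]
    preds <- purrr::map_dfr(sort(unique(fp$fold)), function(f) {
      test_ids <- fp$accession_id[fp$fold == f]
      drop_test <- function(b) b %>% filter(!.data$accession_id %in% test_ids)
      direct <- .fit_and_predict(model, drop_test(adj), test_ids,
                                 G = G, H = H, markers = markers)
      p_lys <- .fit_and_predict(model, drop_test(lys), test_ids,
                                G = G, H = H, markers = markers)
      p_pro <- .fit_and_predict(model, drop_test(pro), test_ids,
                                G = G, H = H, markers = markers)
      p_tgw <- .fit_and_predict(model, drop_test(tg), test_ids,
                                G = G, H = H, markers = markers)
      adj_model <- fit_adjustment(drop_test(lys), drop_test(pro),
                                  drop_test(tg))
      derived <- adjust_lysine(
        p_lys %>% rename(blue = "predicted_value"),
        p_pro %>% rename(blue = "predicted_value"),
        p_tgw %>% rename(blue = "predicted_value"),
        model = adj_model)
      tibble(accession_id = test_ids,
             direct = setNames(direct$predicted_value,
                               direct$accession_id)[test_ids],
             component = setNames(derived$blue,
                                  derived$accession_id)[test_ids])
    })
    tibble(repeat_index = r,
           ability_direct = cor(y_adj[preds$accession_id], preds$direct),
           ability_component = cor(y_adj[preds$accession_id],
                                   preds$component))
  })
  res <- res %>% mutate(difference = .data$ability_direct -
                          .data$ability_component)
  structure(res, class = c("strategy_comparison", class(res)))
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf(
    "Derived-trait strategies over %d repeats:\n  direct %.3f, component-wise %.3f (mean paired difference %+.3f)\n",
    nrow(x), mean(x$ability_direct), mean(x$ability_component),
    mean(x$difference)))
  invisible(x)
}

#' Predict a whole collection from the full training set
#'
#' Fits the chosen model once on all available BLUEs and predicts every
#' genotyped accession; summary statistics are reported separately for
#' accessions with and without training data.
#'
#' @param blues BLUE table (one trait) used as the training set.
#' @param model Model label or [model_spec()].
#' @inheritParams cross_validate
#' @return Object of class `collection_prediction`: `predictions` (tibble
#'   `accession_id, trait, predicted_value, model, in_training`),
#'   `summary` (mean/sd/n per training membership) and the fitted model.
#' @export
predict_collection <- function(blues, model = "egblup", G = NULL, H = NULL,
                               markers = NULL) {
  tab <- .check_blues(blues, "blues")
  trait <- if ("trait" %in% names(tab)) tab$trait[1] else "trait"
  fit <- .fit_model(model, tab, G = G, H = H, markers = markers)
  preds <- predict(fit) %>%
    mutate(trait = trait,
           in_training = .data$accession_id %in% tab$accession_id) %>%
    select("accession_id", "trait", "predicted_value", "model", "in_training")
  summary <- preds %>%
    group_by(.data$trait, .data$in_training) %>%
    summarise(n = dplyr::n(), mean = mean(.data$predicted_value),
              sd = stats::sd(.data$predicted_value), .groups = "drop")
  structure(list(predictions = preds, summary = summary, fit = fit),
            class = "collection_prediction")
}

#' @export
print.collection_prediction <- function(x, ...) {
  cat(sprintf("Collection prediction (%s), %d accessions\n",
              x$fit$model, nrow(x$predictions)))
  print(x$summary)
  invisible(x)
}

#' Culling-level selection on two predicted traits
#'
#' Per trait the threshold is `mean + qnorm(level) * sd` of the predictions
#' over all accessions (normal-quantile culling level); an accession is
#' selected when it exceeds both thresholds. Selections at a more stringent
#' level are always a subset of those at a more relaxed one. An
#' empirical-quantile mode is available behind `mode`.
#'
#' @param predictions Tibble `accession_id, trait, predicted_value`
#'   containing exactly two traits (or a [predict_collection()] result
#'   combined upstream).
#' @param level Cumulative probability of the culling level, in (0.5, 1).
#' @param mode `"normal"` (default) or `"empirical"` quantiles.
#' @return Object of class `selection_result` with `level`, `thresholds`
#'   (named per trait) and `selected` accession labels.
#' @export
culling_select <- function(predictions, level = 0.999,
                           mode = c("normal", "empirical")) {
  mode <- match.arg(mode)
  check_number(level, "level", 0.5, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  if (!all(c("accession_id", "trait", "predicted_value") %in%
           names(predictions))) {
    stop_bad_arg("`predictions` needs columns accession_id, trait, predicted_value")
  }
  traits <- unique(predictions$trait)
  if (length(traits) != 2L) {
    stop_bad_arg(sprintf("culling selection needs exactly 2 traits; got %d",
                         length(traits)))
  }
  wide <- predictions %>%
    select("accession_id", "trait", "predicted_value") %>%
    tidyr::pivot_wider(names_from = "trait", values_from = "predicted_value") %>%
    filter(complete.cases(.))
  thresholds <- vapply(traits, function(t) {
    v <- wide[[t]]
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) {
      stop_bad_arg(sprintf("predictions for %s have zero spread; culling threshold undefined", t))
    }
    if (mode == "normal") mean(v) + qnorm(level) * s
    else unname(quantile(v, level, type = 7))
  }, numeric(1))
  keep <- rep(TRUE, nrow(wide))
  for (t in traits) keep <- keep & wide[[t]] > thresholds[[t]]
  structure(list(level = level, mode = mode,
                 thresholds = setNames(thresholds, traits),
                 selected = wide$accession_id[keep],
                 n_candidates = nrow(wide)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Culling-level selection at %.3f (%s quantiles)\n",
              x$level, x$mode))
  cat(sprintf("  thresholds: %s\n",
              paste(sprintf("%s > %.3f", names(x$thresholds), x$thresholds),
                    collapse = ", ")))
  cat(sprintf("  selected %d of %d accessions%s\n", length(x$selected),
              x$n_candidates,
              if (length(x$selected) > 0 && length(x$selected) <= 25)
                paste0(": ", paste(x$selected, collapse = ", ")) else ""))
  invisible(x)
}

#' Correlation of predicted traits with collecting-site altitude
#'
#' Pearson correlation (with p-value) between each trait's predictions and
#' the altitude of the collecting site, over the accessions with known
#' altitude.
#'
#' @param predictions Tibble `accession_id, trait, predicted_value`.
#' @param passport Tibble `accession_id, altitude` (metres).
#' @return Tibble `trait, n, r, p_value`.
#' @export
altitude_association <- function(predictions, passport) {
  if (!all(c("accession_id", "altitude") %in% names(passport))) {
    stop_bad_arg("`passport` needs columns accession_id, altitude")
  }
  passport <- tibble::as_tibble(passport) %>%
    mutate(accession_id = as.character(.data$accession_id)) %>%
    filter(is.finite(.data$altitude))
  joined <- predictions %>%
    inner_join(passport, by = "accession_id")
  if (dplyr::n_distinct(joined$accession_id) < 3L) {
    stop_bad_arg("fewer than 3 accessions with altitude information")
  }
  purrr::map_dfr(split(joined, joined$trait), function(d) {
    if (stats::sd(d$altitude) < 1e-12) {
      stop_bad_arg("altitude is constant; correlation undefined")
    }
    ct <- cor.test(d$predicted_value, d$altitude)
    tibble(trait = d$trait[1], n = nrow(d),
           r = unname(ct$estimate), p_value = ct$p.value)
  })
}
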