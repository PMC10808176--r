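#' Tidiers for genebankgp result objects
#'
#' broom-style `tidy()` and `glance()` methods: `tidy()` returns the
#' per-accession (or per-term) tibble, `glance()` a one-row model summary.
#'
#' @param x A genebankgp result object.
#' @param ... Unused.
#' @name genebankgp-tidiers
NULL

#' @rdname genebankgp-tidiers
#' @export
tidy.blues_fit <- function(x, ...) x$blues

#' @rdname genebankgp-tidiers
#' @export
glance.blues_fit <- function(x, ...) {
  tibble(trait = x$blues$trait[1],
         n_accessions = nrow(x$blues),
         outliers_removed = x$outliers_removed,
         correction_rounds = x$correction_rounds,
         h2_before = x$h2_before$h2, h2_after = x$h2_after$h2,
         h2_pb_before = x$h2_before$h2_pb, h2_pb_after = x$h2_after$h2_pb,
         sigma_g2 = x$h2_after$sigma_g2,
         sigma_e2_bar = x$h2_after$sigma_e2_bar,
         n_bar = x$h2_after$n_bar)
}

#' @rdname genebankgp-tidiers
#' @export
tidy.year_model_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(effect = "genotype", level = names(x$genotype_effects),
           estimate = unname(x$genotype_effects)),
    tibble(effect = "year", level = names(x$year_effects),
           estimate = unname(x$year_effects)))
}

#' @rdname genebankgp-tidiers
#' @export
glance.year_model_fit <- function(x, ...) {
  tibble(mode = x$mode, trait = x$trait, n_records = x$n_records,
         sigma_g2 = x$sigma_g2, sigma_a2 = x$sigma_a2,
         sigma_e2_bar = x$sigma_e2_bar,
         restricted_log_likelihood = x$restricted_log_likelihood,
         converged = x$converged, n_iter = x$n_iter)
}

#' @rdname genebankgp-tidiers
#' @export
tidy.heritability_stats <- function(x, ...) {
  tibble(h2 = x$h2, h2_pb = x$h2_pb, sigma_g2 = x$sigma_g2,
         sigma_e2_bar = x$sigma_e2_bar, n_bar = x$n_bar)
}

#' @rdname genebankgp-tidiers
#' @export
tidy.adjustment_model <- function(x, ...) {
  tibble(term = c("b_protein", "b_tgw", "mean_protein", "mean_tgw"),
         estimate = c(x$b_protein, x$b_tgw, x$mean_protein, x$mean_tgw))
}

#' @rdname genebankgp-tidiers
#' @export
glance.adjustment_model <- function(x, ...) {
  tibble(n_accessions_fit = x$n_accessions_fit, r2 = x$r2,
         b_protein = x$b_protein, b_tgw = x$b_tgw)
}

#' @rdname genebankgp-tidiers
#' @export
tidy.gp_fit <- function(x, ...) {
  tibble(accession_id = names(x$genetic_values),
         genetic_value = unname(x$genetic_values),
         predicted_value = x$mu_hat + unname(x$genetic_values),
         in_training = names(x$genetic_values) %in% x$training_accessions)
}

#' @rdname genebankgp-tidiers
#' @export
glance.gp_fit <- function(x, ...) {
  vc <- as.list(x$variance_components)
  dplyr::bind_cols(tibble(model = x$model, mu_hat = x$mu_hat,
                          n_training = length(x$training_accessions),
                          converged = isTRUE(x$converged)),
                   tibble::as_tibble(vc))
}

#' @rdname genebankgp-tidiers
#' @export
glance.cv_result <- function(x, ...) attr(x, "summary")

#' @rdname genebankgp-tidiers
#' @export
tidy.pcoa_result <- function(x, ...) {
  dplyr::bind_cols(tibble(accession_id = rownames(x$coordinates)),
                   tibble::as_tibble(x$coordinates))
}

#' @rdname genebankgp-tidiers
#' @export
tidy.selection_result <- function(x, ...) {
  tibble(accession_id = x$selected, level = x$level)
}

#' @rdname genebankgp-tidiers
#' @export
glance.selection_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(level = x$level, mode = x$mode, n_selected = length(x$selected),
           n_candidates = x$n_candidates),
    tibble::as_tibble(as.list(setNames(
      x$thresholds, paste0("threshold_", names(x$thresholds))))))
}
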