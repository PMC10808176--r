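# helpers: a TraitBLUEs table is a tibble with at least accession_id and blue
.check_blues <- function(x, name) {
  if (inherits(x, "blues_fit")) x <- x$blues
  if (!is.data.frame(x) || !all(c("accession_id", "blue") %in% names(x))) {
    stop_bad_arg(sprintf(
      "`%s` must be a BLUE table (columns accession_id, blue) or a blues_fit", name))
  }
  tibble::as_tibble(x) %>%
    mutate(accession_id = as.character(.data$accession_id))
}

#' Fit the lysine adjustment model
#'
#' Ordinary least squares of the lysine BLUEs on the protein and TGW BLUEs
#' (with intercept), restricted to the accessions present in all three
#' tables. The partial regression coefficients and the predictor means over
#' the fitting set define a fixed transformation used by [adjust_lysine()]:
#' `lysine_adj = lysine - b_protein (protein - mean) - b_tgw (tgw - mean)`.
#'
#' @param lysine,protein,tgw BLUE tables (tibbles with `accession_id`,
#'   `blue`) or [compute_blues()] results.
#' @return Object of class `adjustment_model` with `b_protein` (per mille
#'   per percent), `b_tgw` (per mille per gram), `mean_protein`, `mean_tgw`,
#'   `n_accessions_fit` and `r2`.
#' @export
fit_adjustment <- function(lysine, protein, tgw) {
  lys <- .check_blues(lysine, "lysine")
  pro <- .check_blues(protein, "protein")
  tg <- .check_blues(tgw, "tgw")
  common <- lys %>%
    select("accession_id", lysine = "blue") %>%
    inner_join(pro %>% select("accession_id", protein = "blue"),
               by = "accession_id") %>%
    inner_join(tg %>% select("accession_id", tgw = "blue"),
               by = "accession_id")
  if (nrow(common) < 3L) {
    stop_bad_arg(sprintf(
      "need at least 3 accessions with all three traits; found %d", nrow(common)))
  }
  r_pt <- stats::cor(common$protein, common$tgw)
  if (!is.finite(r_pt) || abs(r_pt) >= 1 - 1e-12) {
    stop_bad_arg("protein and TGW BLUEs are collinear; the partial regression is not identifiable")
  }
  fit <- stats::lm(lysine ~ protein + tgw, data = common)
  tss <- sum((common$lysine - mean(common$lysine))^2)
  structure(list(
    b_protein = unname(coef(fit)["protein"]),
    b_tgw = unname(coef(fit)["tgw"]),
    mean_protein = mean(common$protein),
    mean_tgw = mean(common$tgw),
    n_accessions_fit = nrow(common),
    r2 = if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_,
    accessions = common$accession_id
  ), class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("Lysine adjustment (partial regression on protein and TGW)\n")
  cat(sprintf("  b_protein = %.4f per-mille/%%, b_tgw = %.4f per-mille/g\n",
              x$b_protein, x$b_tgw))
  cat(sprintf("  predictor means: protein %.3f %%, TGW %.3f g (n = %d, R2 = %.3f)\n",
              x$mean_protein, x$mean_tgw, x$n_accessions_fit, x$r2))
  invisible(x)
}

#' Adjust lysine content for protein content and grain weight
#'
#' Applies the fitted partial-regression correction genotype-wise:
#' `lysine_adj = lysine - b_protein (protein - mean_protein) -
#' b_tgw (tgw - mean_tgw)`, using the means stored in `model` (so the
#' adjustment is the same fixed transformation for any accession set,
#' including predicted phenotypes). Accessions missing either predictor are
#' excluded with a message.
#'
#' @inheritParams fit_adjustment
#' @param model An [fit_adjustment()] model; fitted on the fly from the
#'   three tables when omitted.
#' @return Tibble `accession_id, trait ("lysine_adjusted"), blue` (plus
#'   `se` copied from the lysine table when present).
#' @export
adjust_lysine <- function(lysine, protein, tgw, model = NULL) {
  if (is.null(model)) model <- fit_adjustment(lysine, protein, tgw)
  stopifnot(inherits(model, "adjustment_model"))
  lys <- .check_blues(lysine, "lysine")
  pro <- .check_blues(protein, "protein")
  tg <- .check_blues(tgw, "tgw")
  joined <- lys %>%
    left_join(pro %>% select("accession_id", protein = "blue"),
              by = "accession_id") %>%
    left_join(tg %>% select("accession_id", tgw = "blue"),
              by = "accession_id")
  missing <- !complete.cases(joined[, c("protein", "tgw")])
  if (any(missing)) {
    inform(sprintf(
      "%d of %d accessions lack protein and/or TGW values and were excluded from the adjustment",
      sum(missing), nrow(joined)))
    joined <- joined[!missing, , drop = FALSE]
  }
  out <- joined %>%
    mutate(blue = .data$blue -
             model$b_protein * (.data$protein - model$mean_protein) -
             model$b_tgw * (.data$tgw - model$mean_tgw),
           trait = "lysine_adjusted") %>%
    select(dplyr::any_of(c("accession_id", "trait", "blue", "se", "n_years")))
  out
}
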