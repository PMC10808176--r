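#' Plot cross-validated prediction abilities per model
#'
#' Boxplots of the per-repeat prediction abilities, one box per model,
#' with the mean marked by a diamond.
#'
#' @param object A [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$model, y = .data$ability)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3) +
    ggplot2::labs(x = NULL, y = "prediction ability (r)",
                  title = unique(object$trait)) +
    ggplot2::theme_minimal()
}

#' Plot the first two principal coordinates
#'
#' @param object A [pcoa()] result.
#' @param colour Optional named vector (by accession) used to colour the
#'   points, e.g. a predicted trait.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  lab <- function(i) sprintf("PCo%d (%.1f%%)", i,
                             100 * object$proportion_explained[i])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2))
  if (!is.null(colour)) {
    df$colour <- unname(colour[df$accession_id])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                          colour = .data$colour))
  }
  p + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot collection predictions split by training membership
#'
#' @param object A [predict_collection()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.collection_prediction <- function(object, ...) {
  df <- object$predictions %>%
    mutate(set = ifelse(.data$in_training, "training", "prediction only"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set,
                                   y = .data$predicted_value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "predicted value") +
    ggplot2::theme_minimal()
}

#' Two-trait culling-level scatter plot
#'
#' Scatter of the two predicted traits with the culling thresholds at the
#' requested levels drawn as lines; selected accessions are highlighted.
#'
#' @param predictions Tibble `accession_id, trait, predicted_value` with
#'   exactly two traits.
#' @param levels Culling levels to draw.
#' @return A ggplot object.
#' @export
plot_culling <- function(predictions, levels = c(0.99, 0.999)) {
  traits <- unique(predictions$trait)
  stopifnot(length(traits) == 2L)
  wide <- predictions %>%
    select("accession_id", "trait", "predicted_value") %>%
    tidyr::pivot_wider(names_from = "trait",
                       values_from = "predicted_value") %>%
    filter(complete.cases(.))
  sels <- lapply(sort(levels), culling_select, predictions = predictions)
  wide$selected <- "no"
  for (s in sels) {
    wide$selected[wide$accession_id %in% s$selected] <-
      sprintf("%.3f", s$level)
  }
  thr <- dplyr::bind_rows(lapply(sels, function(s) {
    tibble(level = sprintf("%.3f", s$level),
           x = s$thresholds[[traits[1]]], y = s$thresholds[[traits[2]]])
  }))
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[traits[1]]],
                                     y = .data[[traits[2]]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 0.8) +
    ggplot2::geom_vline(data = thr,
                        ggplot2::aes(xintercept = .data$x,
                                     linetype = .data$level)) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$y,
                                     linetype = .data$level)) +
    ggplot2::scale_colour_manual(
      values = setNames(c("grey60", "purple", "orange"),
                        c("no", sprintf("%.3f", sort(levels))))) +
    ggplot2::labs(colour = "selected at", linetype = "culling level") +
    ggplot2::theme_minimal()
}
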