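# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad_arg <- function(msg, class = "genebankgp_error") {
  rlang::abort(msg, class = c(class, "genebankgp_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    stop_bad_arg(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s; got %s",
      name,
      if (closed_lower) "[" else "(", format(lower),
      format(upper), if (closed_upper) "]" else ")",
      paste(format(x), collapse = ", ")
    ), class = "genebankgp_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    stop_bad_arg(sprintf("`%s` must be an integer >= %d", name, min),
                 class = "genebankgp_config_error")
  }
  invisible(as.integer(x))
}

# validate a long-format phenotype table; returns it as a tibble with
# character accession_id / year and a single trait unless multi_trait = TRUE
check_phenotypes <- function(table, multi_trait = FALSE) {
  required <- c("accession_id", "year", "trait", "value")
  if (!is.data.frame(table) || !all(required %in% names(table))) {
    stop_bad_arg(paste0(
      "phenotype table must be a data frame with columns ",
      paste(required, collapse = ", ")))
  }
  tab <- tibble::as_tibble(table) %>%
    mutate(accession_id = as.character(.data$accession_id),
           year = as.character(.data$year),
           trait = as.character(.data$trait))
  if (nrow(tab) == 0L) stop_bad_arg("phenotype table is empty")
  if (any(!is.finite(tab$value))) {
    stop_bad_arg("phenotype values must be finite")
  }
  if (!multi_trait && dplyr::n_distinct(tab$trait) != 1L) {
    stop_bad_arg("expected records of a single trait; split by trait first")
  }
  dup <- tab %>% count(.data$accession_id, .data$year, .data$trait) %>%
    filter(n > 1L)
  if (nrow(dup) > 0L) {
    stop_bad_arg(sprintf(
      "duplicated (accession, year, trait) records (e.g. %s / %s / %s); the design has one measurement per year",
      dup$accession_id[1], dup$year[1], dup$trait[1]))
  }
  tab
}

check_genotypes <- function(geno, allow_missing = FALSE) {
  if (!is.matrix(geno) || !is.numeric(geno)) {
    stop_bad_arg("genotypes must be a numeric matrix (accessions x markers)")
  }
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop_bad_arg("genotype matrix needs accession rownames and marker colnames")
  }
  vals <- geno[!is.na(geno)]
  if (!all(vals %in% c(0, 1, 2))) {
    stop_bad_arg("genotype codes must be 0, 1, 2 or NA")
  }
  if (!allow_missing && anyNA(geno)) {
    stop_bad_arg("genotype matrix contains missing codes; impute first (filter_markers)")
  }
  invisible(geno)
}

check_kinship <- function(K, name = "K") {
  if (!is.matrix(K) || nrow(K) != ncol(K) ||
      is.null(rownames(K)) || !identical(rownames(K), colnames(K))) {
    stop_bad_arg(sprintf("`%s` must be a square labeled kinship matrix", name))
  }
  if (max(abs(K - t(K))) > 1e-8) {
    stop_bad_arg(sprintf("`%s` is not symmetric", name))
  }
  invisible(K)
}
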