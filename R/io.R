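#' Read and write long-format phenotype records
#'
#' The on-disk format is a CSV with header
#' `accession_id,year,trait,value`, one row per accession x year x trait.
#'
#' @param path File path.
#' @return [read_phenotypes()]: a validated tibble.
#' @export
read_phenotypes <- function(path) {
  tab <- tibble::as_tibble(read.csv(path, colClasses = c(
    accession_id = "character", year = "character",
    trait = "character", value = "numeric")))
  check_phenotypes(tab, multi_trait = TRUE)
}

#' @rdname read_phenotypes
#' @param table Phenotype tibble.
#' @export
write_phenotypes <- function(table, path) {
  check_phenotypes(table, multi_trait = TRUE)
  write.csv(table[, c("accession_id", "year", "trait", "value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV or VCF
#'
#' TSV layout: rows are accessions (first column the accession id), columns
#' are marker ids, cells the 0/1/2 codes (empty or `NA` for missing). VCF
#' ingestion (requires the vcfR package) converts diploid GT fields to
#' alternative-allele counts; half-missing calls become missing.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`; guessed from the extension by default.
#' @return Integer matrix (accessions x markers) with dimnames.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop_bad_arg("VCF ingestion needs the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    ids <- rownames(gt)
    if (is.null(ids)) ids <- paste0("M", seq_len(nrow(gt)))
    counts <- function(x) {
      x <- sub(":.*", "", x)
      a <- strsplit(x, "[/|]")
      vapply(a, function(al) {
        if (any(al %in% c(".", ""))) return(NA_integer_)
        sum(al != "0")
      }, integer(1))
    }
    codes <- t(apply(gt, 1L, counts))
    geno <- t(codes)
    dimnames(geno) <- list(colnames(gt), ids)
  } else {
    raw <- read.delim(path, check.names = FALSE, row.names = 1L)
    geno <- as.matrix(raw)
    storage.mode(geno) <- "integer"
  }
  check_genotypes(geno, allow_missing = TRUE)
  geno
}

#' @rdname read_genotypes
#' @param genotypes Matrix to write (TSV with accession ids in the first
#'   column).
#' @export
write_genotypes <- function(genotypes, path) {
  check_genotypes(genotypes, allow_missing = TRUE)
  df <- data.frame(accession_id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write labeled symmetric matrices (kinship / distance)
#'
#' @param x Labeled square matrix.
#' @param path File path (TSV, labels in first row and column).
#' @export
write_kinship <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  raw <- read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(raw)
  dimnames(m) <- list(rownames(raw), colnames(raw))
  check_kinship(m, "kinship file")
  m
}

#' Write a BLUE table as CSV
#'
#' Columns `accession_id, trait, blue, se, n_years`.
#'
#' @param blues BLUE tibble or [compute_blues()] result.
#' @param path File path.
#' @export
write_blues <- function(blues, path) {
  tab <- .check_blues(blues, "blues")
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_blues
#' @export
read_blues <- function(path) {
  tibble::as_tibble(read.csv(path, colClasses = c(accession_id = "character")))
}
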