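#' Filter and impute a raw biallelic marker matrix
#'
#' Applies the marker quality rules in a fixed order: (1) drop monomorphic
#' markers (every non-missing call the same homozygote); (2) drop markers
#' with a missing-call fraction above `missing_max`; (3) drop markers whose
#' rarer homozygote class makes up less than `hom_count_min` of the
#' non-missing calls; (4) drop markers with a heterozygote fraction above
#' `het_max`; (5) impute remaining missing calls to the homozygous code of
#' the marker's more frequent (dominant) allele; (6) drop markers whose
#' post-imputation minor allele frequency falls below `maf_min`.
#'
#' @param genotypes Matrix (accessions x markers) with codes 0/1/2/`NA`.
#' @param missing_max,hom_count_min,het_max,maf_min Thresholds of rules
#'   2, 3, 4 and 6.
#' @return A list with `genotypes` (filtered, fully imputed matrix carrying
#'   an `allele_freqs` attribute) and `report` (class `filter_report`: a
#'   tibble of per-rule removals plus `n_markers_in` / `n_markers_out`).
#' @export
filter_markers <- function(genotypes, missing_max = 0.10,
                           hom_count_min = 0.10, het_max = 0.01,
                           maf_min = 0.01) {
  check_genotypes(genotypes, allow_missing = TRUE)
  for (nm in c("missing_max", "hom_count_min", "het_max", "maf_min")) {
    check_number(get(nm), nm, 0, 1)
  }
  m_in <- ncol(genotypes)
  removals <- tibble(rule = character(0), markers_removed = integer(0))
  note_rule <- function(rule, dropped) {
    removals <<- dplyr::bind_rows(removals,
                                  tibble(rule = rule,
                                         markers_removed = length(dropped)))
    if (length(dropped) > 0L) {
      genotypes <<- genotypes[, -dropped, drop = FALSE]
    }
  }
  frac <- function(f) apply(genotypes, 2L, f)

  mono <- which(frac(function(x) {
    x <- x[!is.na(x)]
    length(x) > 0L && length(unique(x)) == 1L && x[1] %in% c(0, 2)
  }))
  note_rule("monomorphic", mono)

  miss <- which(colMeans(is.na(genotypes)) > missing_max)
  note_rule("missing_fraction", miss)

  lowhom <- which(frac(function(x) {
    x <- x[!is.na(x)]
    min(sum(x == 0), sum(x == 2)) / length(x) < hom_count_min
  }))
  note_rule("minor_homozygote_count", lowhom)

  het <- which(frac(function(x) {
    x <- x[!is.na(x)]
    mean(x == 1) > het_max
  }))
  note_rule("heterozygosity", het)

  if (ncol(genotypes) > 0L && anyNA(genotypes)) {
    p <- colMeans(genotypes, na.rm = TRUE) / 2
    fill <- ifelse(p > 0.5, 2, 0)   # dominant-allele homozygote
    idx <- which(is.na(genotypes), arr.ind = TRUE)
    genotypes[idx] <- fill[idx[, 2L]]
  }

  if (ncol(genotypes) > 0L) {
    p <- colMeans(genotypes) / 2
    lowmaf <- which(pmin(p, 1 - p) < maf_min)
  } else lowmaf <- integer(0)
  note_rule("maf", lowmaf)

  if (ncol(genotypes) == 0L) {
    stop_bad_arg("all markers were removed by the quality filters")
  }
  attr(genotypes, "allele_freqs") <- colMeans(genotypes) / 2
  report <- structure(list(
    removals = removals,
    n_markers_in = m_in,
    n_markers_out = ncol(genotypes)
  ), class = "filter_report")
  list(genotypes = genotypes, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Marker filtering: %d in -> %d out\n",
              x$n_markers_in, x$n_markers_out))
  for (i in seq_len(nrow(x$removals))) {
    cat(sprintf("  %-24s %d removed\n", x$removals$rule[i],
                x$removals$markers_removed[i]))
  }
  invisible(x)
}

#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum_k p_k (1 - p_k))` where `Z` holds the marker codes
#' centered by twice the alternative-allele frequency.
#'
#' @param genotypes Imputed matrix (accessions x markers, codes 0/1/2).
#' @return Labeled symmetric matrix with attribute `kind = "additive"`.
#' @export
compute_grm <- function(genotypes) {
  check_genotypes(genotypes)
  p <- colMeans(genotypes) / 2
  poly <- sum(p > 0 & p < 1)
  if (poly < 2L) {
    stop_bad_arg("need at least 2 polymorphic markers to build G")
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop_bad_arg("no marker polymorphism; G is undefined")
  Z <- sweep(genotypes, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  attr(G, "kind") <- "additive"
  G
}

#' Epistatic (additive-by-additive) relationship matrix
#'
#' The Hadamard square of the additive matrix: `H[i, j] = G[i, j]^2`.
#' Positive semidefiniteness is inherited from `G` (Schur product theorem).
#'
#' @param G Additive kinship from [compute_grm()].
#' @return Labeled symmetric matrix with attribute `kind = "epistatic"`.
#' @export
compute_epistatic <- function(G) {
  check_kinship(G, "G")
  if (!identical(attr(G, "kind"), "additive")) {
    stop_bad_arg("`G` must be an additive kinship (attr kind = 'additive')")
  }
  H <- G * G
  attr(H, "kind") <- "epistatic"
  H
}

#' Rogers' genetic distances between genomic profiles
#'
#' For biallelic loci with individual allele frequencies in \{0, 1/2, 1\}
#' (codes 0/1/2), the per-locus Rogers' distance reduces to half the
#' absolute code difference; the overall distance is its mean across loci,
#' bounded in \[0, 1\].
#'
#' @param genotypes Imputed matrix (accessions x markers).
#' @return Symmetric labeled distance matrix with zero diagonal.
#' @export
rogers_distance <- function(genotypes) {
  check_genotypes(genotypes)
  D <- as.matrix(dist(genotypes / 2, method = "manhattan")) / ncol(genotypes)
  dimnames(D) <- list(rownames(genotypes), rownames(genotypes))
  D
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: double-center `-D^2/2`, eigendecompose, and
#' scale the eigenvectors by the square roots of the positive eigenvalues.
#' Axes are ordered by eigenvalue; negative eigenvalues are dropped and the
#' proportion of variation explained is computed over the positive ones.
#'
#' @param distances Square symmetric matrix with zero diagonal.
#' @param n_axes Number of coordinate axes requested.
#' @return Object of class `pcoa_result` with `coordinates` (accessions x
#'   axes), `eigenvalues` (all, descending) and `proportion_explained`
#'   (per returned axis).
#' @export
pcoa <- function(distances, n_axes = 2L) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances)) {
    stop_bad_arg("`distances` must be a square matrix")
  }
  if (max(abs(distances - t(distances))) > 1e-8 ||
      max(abs(diag(distances))) > 1e-8) {
    stop_bad_arg("`distances` must be symmetric with zero diagonal")
  }
  n_axes <- check_count(n_axes, "n_axes", min = 1L)
  n <- nrow(distances)
  sc <- suppressWarnings(
    cmdscale(distances, k = min(n_axes, n - 1L), eig = TRUE))
  eig <- sort(sc$eig, decreasing = TRUE)
  n_pos <- sum(eig > 1e-8)
  if (n_axes > n_pos) {
    warn(sprintf(
      "only %d positive eigenvalues; returning %d axes instead of %d",
      n_pos, n_pos, n_axes))
    n_axes <- n_pos
  }
  coords <- sc$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  rownames(coords) <- rownames(distances)
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    proportion_explained = eig[seq_len(n_axes)] / sum(eig[eig > 0])
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d points, %d axes (%.1f%% of positive-eigenvalue variation)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$proportion_explained)))
  invisible(x)
}
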