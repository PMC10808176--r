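# fixtures built in code, shared across test files

# a small inbred genotype matrix with clean filtering behavior
quick_geno <- function(n = 50, m = 100, seed = 11, ...) {
  cfg <- sim_config(n_accessions = n, n_markers = m, seed = seed, ...)
  simulate_genotypes(cfg)
}

# BLUE-level phenotypes consistent with an additive architecture on `geno`:
# y = 10 + g + e with var(g)/var(y) targeting h2
blue_phenotypes <- function(geno, h2 = 0.5, seed = 1, trait = "trait") {
  set.seed(seed)
  Zc <- sweep(geno, 2L, colMeans(geno))
  g <- drop(Zc %*% rnorm(ncol(geno)))
  g <- g / stats::sd(g)
  e <- rnorm(nrow(geno), 0, sqrt((1 - h2) / h2))
  list(blues = tibble::tibble(accession_id = rownames(geno), trait = trait,
                              blue = 10 + g + e),
       g = stats::setNames(g, rownames(geno)))
}

# balanced two-genotype x two-year toy records
balanced_toy <- function(noise_sd = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(accession_id = c("g1", "g2", "g3"),
                      year = c("Y1", "Y2"), stringsAsFactors = FALSE)
  g <- c(g1 = 0, g2 = 1, g3 = 2)
  a <- c(Y1 = 1, Y2 = -1)
  tibble::tibble(accession_id = grid$accession_id, year = grid$year,
                 trait = "toy",
                 value = g[grid$accession_id] + a[grid$year] +
                   rnorm(nrow(grid), 0, noise_sd))
}

# independent Holm step-down oracle: flags indices by textbook sorting
holm_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  keep <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) keep[ord[i]] <- TRUE else break
  }
  which(keep)
}

# brute-force Rogers' distance over loci from individual allele frequencies
rogers_oracle <- function(geno) {
  n <- nrow(geno)
  L <- ncol(geno)
  D <- matrix(0, n, n, dimnames = list(rownames(geno), rownames(geno)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (l in seq_len(L)) {
      p_i <- geno[i, l] / 2
      p_j <- geno[j, l] / 2
      acc <- acc + sqrt(0.5 * ((p_i - p_j)^2 + ((1 - p_i) - (1 - p_j))^2))
    }
    D[i, j] <- acc / L
  }
  D
}

# VanRaden method-1 G computed step by step, independently of compute_grm
grm_oracle <- function(geno) {
  p <- colMeans(geno) / 2
  Z <- sweep(geno, 2L, 2 * p)
  (Z %*% t(Z)) / (2 * sum(p * (1 - p)))
}
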