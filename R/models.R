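# shared helpers for the genomic prediction models

.training_data <- function(blues, labels, what = "kinship") {
  tab <- .check_blues(blues, "blues")
  missing <- setdiff(tab$accession_id, labels)
  if (length(missing) > 0L) {
    stop_bad_arg(sprintf(
      "%d training accessions absent from the %s matrix (e.g. %s)",
      length(missing), what, paste(head(missing, 3), collapse = ", ")))
  }
  y <- setNames(tab$blue, tab$accession_id)
  if (length(y) < 3L) stop_bad_arg("need at least 3 training accessions")
  if (stats::var(y) <= 0) {
    stop_bad_arg("training phenotypes have zero variance")
  }
  y
}

.new_gp_fit <- function(...) structure(list(...), class = "gp_fit")

#' G-BLUP: genomic best linear unbiased prediction
#'
#' Fits `y = 1 mu + g + e` with `g ~ N(0, G sigma_g2)` and
#' `e ~ N(0, I sigma_e2)`. The variance components are estimated by REML
#' through the eigendecomposition of the training block of `G` (the
#' restricted likelihood is profiled down to a one-dimensional search over
#' the variance ratio). Genetic values for every accession in `G` --
#' including unphenotyped ones -- follow from the BLUP conditional
#' expectation `g_all = G[all, train] (G[train, train] + delta I)^{-1}
#' (y - mu)` with `delta = sigma_e2 / sigma_g2`.
#'
#' @param blues BLUE table (tibble with `accession_id`, `blue`) or
#'   [compute_blues()] result; training set.
#' @param G Additive kinship from [compute_grm()] covering at least the
#'   training accessions.
#' @return Object of class `gp_fit` with `mu_hat`, `genetic_values` (all
#'   accessions of `G`), `variance_components` and `h2`.
#' @export
fit_gblup <- function(blues, G) {
  check_kinship(G, "G")
  y <- .training_data(blues, rownames(G))
  train <- names(y)
  Gtt <- G[train, train, drop = FALSE]
  ed <- eigen(Gtt, symmetric = TRUE)
  if (min(ed$values) < -1e-6 * max(abs(ed$values), 1)) {
    stop_bad_arg("`G` is not positive semidefinite within tolerance")
  }
  d <- pmax(ed$values, 0)
  n <- length(y)
  yt <- drop(crossprod(ed$vectors, y))
  xt <- drop(crossprod(ed$vectors, rep(1, n)))
  prof <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    sxx <- sum(w * xt^2)
    mu <- sum(w * xt * yt) / sxx
    rss <- sum(w * (yt - xt * mu)^2)
    s2g <- rss / (n - 1)
    ll <- -0.5 * (sum(log(d + delta)) + (n - 1) * log(s2g) + log(sxx) + (n - 1))
    list(ll = ll, mu = mu, s2g = s2g, delta = delta)
  }
  opt <- optimize(function(p) -prof(p)$ll, lower = log(1e-6), upper = log(1e6),
                  tol = 1e-10)
  # refinement pass on a narrow bracket sharpens the flat-optimum precision
  opt <- optimize(function(p) -prof(p)$ll,
                  lower = opt$minimum - 1e-4, upper = opt$minimum + 1e-4,
                  tol = .Machine$double.eps^0.75)
  sol <- prof(opt$minimum)
  sigma_g2 <- sol$s2g
  sigma_e2 <- sol$delta * sigma_g2
  alpha <- drop(ed$vectors %*% ((yt - xt * sol$mu) / (d + sol$delta)))
  g_all <- drop(G[, train, drop = FALSE] %*% alpha)
  .new_gp_fit(
    model = "gblup",
    mu_hat = sol$mu,
    genetic_values = setNames(g_all, rownames(G)),
    variance_components = c(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2),
    h2 = sigma_g2 / (sigma_g2 + sigma_e2),
    restricted_log_likelihood = sol$ll,
    converged = TRUE,
    training_accessions = train)
}

#' EG-BLUP: G-BLUP extended by additive-by-additive epistasis
#'
#' Fits `y = 1 mu + g + g1 + e` with `g ~ N(0, G sigma_g2)` and
#' `g1 ~ N(0, H sigma_g1_2)` where `H = G # G` (Hadamard square). The two
#' variance ratios are estimated by derivative-free REML (Nelder-Mead on
#' the log-ratios, multi-start) with the residual variance profiled out;
#' predictions use the two-kernel BLUP conditional expectation and report
#' the additive and epistatic components separately.
#'
#' @inheritParams fit_gblup
#' @param H Epistatic kinship from [compute_epistatic()]; labels must be
#'   identical to `G`'s.
#' @param n_starts Number of Nelder-Mead starts.
#' @param theta_h_fixed Optionally pin the epistatic variance ratio
#'   `sigma_g1_2 / sigma_e2` (0 reduces the model to G-BLUP exactly).
#' @return Object of class `gp_fit`; `genetic_values` holds `g + g1` and
#'   components `g`/`g1` sit in `genetic_components`.
#' @export
fit_egblup <- function(blues, G, H, n_starts = 3L, theta_h_fixed = NULL) {
  check_kinship(G, "G")
  check_kinship(H, "H")
  if (!identical(rownames(G), rownames(H))) {
    stop_bad_arg("`G` and `H` must be labeled identically")
  }
  y <- .training_data(blues, rownames(G))
  train <- names(y)
  n <- length(y)
  Gtt <- G[train, train, drop = FALSE]
  Htt <- H[train, train, drop = FALSE]
  ones <- rep(1, n)
  profile <- function(theta_g, theta_h) {
    K <- theta_g * Gtt + theta_h * Htt + diag(n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Kinv_y <- backsolve(ch, forwardsolve(t(ch), y))
    Kinv_1 <- backsolve(ch, forwardsolve(t(ch), ones))
    sxx <- sum(ones * Kinv_1)
    mu <- sum(ones * Kinv_y) / sxx
    r <- y - mu
    Kinv_r <- Kinv_y - mu * Kinv_1
    rss <- sum(r * Kinv_r)
    s2e <- rss / (n - 1)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + (n - 1) * log(s2e) +
                    log(sxx) + (n - 1))
    list(ll = ll, mu = mu, s2e = s2e, alpha = Kinv_r)
  }
  fixed_h <- !is.null(theta_h_fixed)
  negll <- function(par) {
    tg <- exp(par[1])
    th <- if (fixed_h) theta_h_fixed else exp(par[2])
    pr <- profile(tg, th)
    if (is.null(pr)) return(1e10)
    -pr$ll
  }
  starts <- list(c(log(0.5), log(0.1)), c(log(0.1), log(0.5)),
                 c(log(0.3), log(0.3)))
  starts <- starts[seq_len(max(1L, min(n_starts, 3L)))]
  if (fixed_h) starts <- lapply(starts, function(s) s[1])
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    op <- if (length(s) == 1L) {
      o <- optimize(function(p) negll(p), lower = log(1e-6), upper = log(1e6),
                    tol = 1e-10)
      o <- optimize(function(p) negll(p), lower = o$minimum - 1e-4,
                    upper = o$minimum + 1e-4, tol = .Machine$double.eps^0.75)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      optim(s, negll, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-10))
    }
    if (is.null(best) || op$value < best$value) best <- op
    if (op$convergence == 0L) converged <- TRUE
  }
  theta_g <- exp(best$par[1])
  theta_h <- if (fixed_h) theta_h_fixed else exp(best$par[2])
  pr <- profile(theta_g, theta_h)
  sigma_e2 <- pr$s2e
  sigma_g2 <- theta_g * sigma_e2
  sigma_g1_2 <- theta_h * sigma_e2
  alpha <- setNames(pr$alpha, train)
  g_add <- drop(theta_g * G[, train, drop = FALSE] %*% alpha)
  g_epi <- drop(theta_h * H[, train, drop = FALSE] %*% alpha)
  .new_gp_fit(
    model = "egblup",
    mu_hat = pr$mu,
    genetic_values = setNames(g_add + g_epi, rownames(G)),
    genetic_components = list(g = setNames(g_add, rownames(G)),
                              g1 = setNames(g_epi, rownames(G))),
    variance_components = c(sigma_g2 = sigma_g2, sigma_g1_2 = sigma_g1_2,
                            sigma_e2 = sigma_e2),
    h2 = (sigma_g2 + sigma_g1_2) / (sigma_g2 + sigma_g1_2 + sigma_e2),
    restricted_log_likelihood = pr$ll,
    converged = converged,
    training_accessions = train)
}

#' Settings for the Bayesian whole-genome regressions
#'
#' @param model `"bayes_a"` or `"bayesian_lasso"`.
#' @param chain_length,burn_in,thin Gibbs chain settings.
#' @param prior_df Degrees of freedom of the scaled-t marker-effect prior
#'   (Bayes A); must exceed 2 for a finite prior variance.
#' @param prior_r2 Heuristic fraction of the phenotypic variance attributed
#'   to the markers when setting prior scales.
#' @param lambda_fixed Optional fixed value for the Bayesian Lasso
#'   regularization parameter `lambda` (skips its Gamma hyperprior update).
#' @param seed Integer RNG seed; chains are reproducible given the seed.
#' @return Validated list of class `model_spec`.
#' @export
model_spec <- function(model = c("bayes_a", "bayesian_lasso"),
                       chain_length = 12000L, burn_in = 2000L, thin = 5L,
                       prior_df = 5, prior_r2 = 0.5, lambda_fixed = NULL,
                       seed = 1L) {
  model <- match.arg(model)
  chain_length <- check_count(chain_length, "chain_length")
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  thin <- check_count(thin, "thin")
  if (burn_in >= chain_length) {
    stop_bad_arg("`burn_in` must be smaller than `chain_length`",
                 class = "genebankgp_config_error")
  }
  if (prior_df <= 2) {
    stop_bad_arg("`prior_df` must exceed 2 for a finite prior variance",
                 class = "genebankgp_config_error")
  }
  check_number(prior_r2, "prior_r2", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  structure(list(model = model, chain_length = chain_length,
                 burn_in = burn_in, thin = thin, prior_df = prior_df,
                 prior_r2 = prior_r2, lambda_fixed = lambda_fixed,
                 seed = as.integer(seed)),
            class = "model_spec")
}

# centered marker matrix (same coding as Z inside G) and training rows
.marker_design <- function(blues, markers) {
  check_genotypes(markers)
  y <- .training_data(blues, rownames(markers), what = "marker")
  p <- colMeans(markers) / 2
  Z_all <- sweep(markers, 2L, 2 * p)
  list(y = y, Z_all = Z_all, Z = Z_all[names(y), , drop = FALSE])
}

#' Bayes A whole-genome regression
#'
#' Gibbs sampler for `y = 1 mu + Z beta + e` where each marker effect has
#' its own variance with a scaled-inverse-chi-square prior (equivalently, a
#' scaled-t prior on the effect). Prior scales follow the usual heuristic:
#' a fraction `prior_r2` of the phenotypic variance is attributed to the
#' markers.
#'
#' @inheritParams fit_gblup
#' @param markers Imputed genotype matrix covering the training accessions
#'   (centered internally by twice the allele frequency, the same coding as
#'   in `G`).
#' @param spec A [model_spec()].
#' @return Object of class `gp_fit` with posterior-mean `mu_hat`,
#'   `marker_effect_means`, `genetic_values` for every genotyped accession,
#'   `variance_components` and chain diagnostics.
#' @export
fit_bayes_a <- function(blues, markers, spec = model_spec("bayes_a")) {
  stopifnot(inherits(spec, "model_spec"))
  md <- .marker_design(blues, markers)
  y <- md$y
  vy <- stats::var(y)
  msx <- sum(apply(md$Z, 2L, stats::var))
  nu <- spec$prior_df
  Sb <- vy * spec$prior_r2 / msx * (nu - 2) / nu
  df_e <- 5
  Se <- vy * (1 - spec$prior_r2) * (df_e - 2) / df_e
  set.seed(spec$seed)
  out <- gibbs_bayes_a(unname(y), md$Z, spec$chain_length, spec$burn_in,
                       spec$thin, nu, Sb, df_e, Se)
  beta <- setNames(out$beta, colnames(markers))
  gv <- drop(md$Z_all %*% beta)
  s2e <- out$sigma2e_samples
  .new_gp_fit(
    model = "bayes_a",
    mu_hat = out$mu,
    genetic_values = setNames(gv, rownames(markers)),
    marker_effect_means = beta,
    marker_effect_sds = setNames(out$beta_sd, colnames(markers)),
    variance_components = c(sigma_g2 = stats::var(gv[names(y)]),
                            sigma_e2 = mean(s2e)),
    convergence_diagnostics = list(
      n_saved = out$n_saved,
      sigma2e_mean = mean(s2e), sigma2e_sd = stats::sd(s2e)),
    sigma2e_samples = s2e,
    converged = TRUE,
    training_accessions = names(y),
    spec = spec)
}

#' Bayesian Lasso whole-genome regression
#'
#' Park-Casella hierarchy: `beta_k ~ N(0, tau_k^2 sigma_e2)` with
#' exponential mixing variances `tau_k^2` (yielding the double-exponential
#' marginal prior) and a Gamma hyperprior on `lambda^2` unless
#' `spec$lambda_fixed` pins it.
#'
#' @inheritParams fit_bayes_a
#' @return Object of class `gp_fit` (see [fit_bayes_a()]).
#' @export
fit_bayesian_lasso <- function(blues, markers,
                               spec = model_spec("bayesian_lasso")) {
  stopifnot(inherits(spec, "model_spec"))
  md <- .marker_design(blues, markers)
  y <- md$y
  vy <- stats::var(y)
  msx <- sum(apply(md$Z, 2L, stats::var))
  df_e <- 5
  Se <- vy * (1 - spec$prior_r2) * (df_e - 2) / df_e
  lambda_fixed <- !is.null(spec$lambda_fixed)
  lambda2_init <- if (lambda_fixed) spec$lambda_fixed^2 else
    2 * (1 - spec$prior_r2) / spec$prior_r2 * msx
  # heuristic prior expectation for lambda^2 (shape/rate of the Gamma)
  shape <- 1.1
  rate <- shape / max(lambda2_init, 1e-8)
  set.seed(spec$seed)
  out <- gibbs_bayesian_lasso(unname(y), md$Z, spec$chain_length,
                              spec$burn_in, spec$thin, lambda2_init,
                              lambda_fixed, shape, rate, df_e, Se)
  beta <- setNames(out$beta, colnames(markers))
  gv <- drop(md$Z_all %*% beta)
  s2e <- out$sigma2e_samples
  .new_gp_fit(
    model = "bayesian_lasso",
    mu_hat = out$mu,
    genetic_values = setNames(gv, rownames(markers)),
    marker_effect_means = beta,
    marker_effect_sds = setNames(out$beta_sd, colnames(markers)),
    variance_components = c(sigma_g2 = stats::var(gv[names(y)]),
                            sigma_e2 = mean(s2e)),
    convergence_diagnostics = list(
      n_saved = out$n_saved,
      sigma2e_mean = mean(s2e), sigma2e_sd = stats::sd(s2e),
      lambda2_mean = mean(out$lambda2_samples)),
    sigma2e_samples = s2e,
    converged = TRUE,
    training_accessions = names(y),
    spec = spec)
}

#' Predicted phenotypes from a fitted genomic prediction model
#'
#' `mu_hat + genetic value` for the requested accessions (all accessions of
#' the model's kinship / marker space by default, so training accessions
#' can be scored in cross-validation).
#'
#' @param object A `gp_fit`.
#' @param accessions Accession labels; default all known to the model.
#' @param ... Unused.
#' @return Tibble `accession_id, predicted_value, model`.
#' @export
predict.gp_fit <- function(object, accessions = NULL, ...) {
  known <- names(object$genetic_values)
  if (is.null(accessions)) accessions <- known
  missing <- setdiff(accessions, known)
  if (length(missing) > 0L) {
    stop_bad_arg(sprintf(
      "unknown accession label(s): %s", paste(head(missing, 5), collapse = ", ")))
  }
  tibble(accession_id = accessions,
         predicted_value = object$mu_hat + unname(object$genetic_values[accessions]),
         model = object$model)
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("Genomic prediction fit: %s\n", x$model))
  cat(sprintf("  %d training accessions, %d with genetic values\n",
              length(x$training_accessions), length(x$genetic_values)))
  cat(sprintf("  mu_hat = %.4f\n", x$mu_hat))
  vc <- x$variance_components
  cat(sprintf("  variance components: %s\n",
              paste(sprintf("%s = %.4g", names(vc), vc), collapse = ", ")))
  invisible(x)
}
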