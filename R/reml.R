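# REML engine for the year model y = Xb + sum_k Z_k u_k + e with
# Var(u_k) = sigma_k^2 I and year-specific residual variances
# Var(e_i) = sigma_{j(i)}^2. Estimation by EM on the mixed-model
# equations; each iteration solves the MME once, so the cost is governed
# by the number of accessions, not the number of records. The restricted
# log-likelihood is monotone non-decreasing along EM iterations. EM
# approaches a zero-variance boundary only geometrically, so when the
# iteration cap is hit, each component is tested against the boundary
# directly (the pin is kept when it raises the restricted likelihood) and
# EM resumes; a Nelder-Mead polish on the log-variances is the last
# resort.

# assemble the MME coefficient matrix and solve; returns everything the EM
# update and the restricted log-likelihood need
.mme_solve <- function(y, W, ranef_idx, year_idx, sigma_r2, sigma_j2) {
  rinv <- 1 / sigma_j2[year_idx]
  WtRi <- Matrix::t(W * rinv)           # (p+q) x n, rows scaled
  C <- as.matrix(WtRi %*% W)
  for (k in seq_along(ranef_idx)) {
    idx <- ranef_idx[[k]]
    C[cbind(idx, idx)] <- C[cbind(idx, idx)] + 1 / sigma_r2[k]
  }
  rhs <- as.numeric(WtRi %*% y)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stop_bad_arg("mixed-model equations are singular; the fixed-effects design is aliased")
  }
  Cinv <- chol2inv(ch)
  sol <- drop(Cinv %*% rhs)
  ehat <- as.numeric(y - W %*% sol)
  logdetC <- 2 * sum(log(diag(ch)))
  # y'Py via the all-positive decomposition e'R^-1 e + u'G^-1 u (the
  # direct form y'R^-1 ehat cancels catastrophically when a year variance
  # sits at the boundary)
  yPy <- sum(rinv * ehat^2)
  for (k in seq_along(ranef_idx)) {
    u <- sol[ranef_idx[[k]]]
    yPy <- yPy + sum(u^2) / sigma_r2[k]
  }
  list(sol = sol, Cinv = Cinv, ehat = ehat, logdetC = logdetC, yPy = yPy)
}

.reml_loglik <- function(ms, ranef_idx, year_idx, sigma_r2, sigma_j2,
                         n_levels) {
  -0.5 * (sum(log(sigma_j2[year_idx])) +
            sum(n_levels * log(sigma_r2)) +
            ms$logdetC + ms$yPy)
}

# y numeric; X, Zlist sparse design matrices; year_idx integer year of each
# record; returns variance components, solutions and the restricted loglik
reml_year_model <- function(y, X, Zlist, year_idx, n_years,
                            tol = 1e-8, max_iter = 2000L, clamp = 1e-10) {
  n <- length(y)
  W <- do.call(cbind, c(list(X), Zlist))
  p <- ncol(X)
  q <- vapply(Zlist, ncol, 1L)
  offs <- p + c(0L, cumsum(q))[seq_along(q)]
  ranef_idx <- lapply(seq_along(Zlist), function(k) offs[k] + seq_len(q[k]))
  n_j <- tabulate(year_idx, n_years)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) {
    stop_bad_arg("phenotype values have zero variance; nothing to fit")
  }
  clamp <- max(clamp, 1e-4 * vy)
  # a variance below 0.1% of the phenotypic variance is heading for the
  # zero boundary; jump there (and stay: EM would otherwise cycle across
  # the trigger) instead of letting it crawl
  floor_trigger <- 1e-3 * vy
  sigma_r2 <- rep(vy / (length(Zlist) + 1), length(Zlist))
  sigma_j2 <- rep(vy / (length(Zlist) + 1), n_years)
  pinned_r <- logical(length(sigma_r2))
  pinned_j <- logical(n_years)
  ll_at <- function(sr, sj) {
    ms <- .mme_solve(y, W, ranef_idx, year_idx, sr, sj)
    .reml_loglik(ms, ranef_idx, year_idx, sr, sj, q)
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  em_phase <- function(iters) {
    ll_old <- if (length(ll_trace)) ll_trace[length(ll_trace)] else -Inf
    for (it in seq_len(iters)) {
      ms <- .mme_solve(y, W, ranef_idx, year_idx, sigma_r2, sigma_j2)
      ll <- .reml_loglik(ms, ranef_idx, year_idx, sigma_r2, sigma_j2, q)
      ll_trace[length(ll_trace) + 1L] <<- ll
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        converged <<- TRUE
        return(invisible(NULL))
      }
      ll_old <- ll
      # EM updates: PEV blocks sit in C^{-1}
      for (k in seq_along(ranef_idx)) {
        if (pinned_r[k]) next
        idx <- ranef_idx[[k]]
        u <- ms$sol[idx]
        upd <- (sum(u^2) + sum(diag(ms$Cinv)[idx])) / q[k]
        if (upd < floor_trigger) {
          pinned_r[k] <<- TRUE
          sigma_r2[k] <<- clamp
        } else sigma_r2[k] <<- upd
      }
      WC <- as.matrix(W %*% ms$Cinv)
      dwcw <- rowSums(WC * as.matrix(W))
      contrib <- ms$ehat^2 + dwcw
      upd_j <- as.numeric(tapply(
        contrib, factor(year_idx, levels = seq_len(n_years)), sum)) / n_j
      newly <- !pinned_j & upd_j < floor_trigger
      pinned_j[newly] <<- TRUE
      sigma_j2 <<- ifelse(pinned_j, clamp, upd_j)
    }
    invisible(NULL)
  }
  em_phase(max_iter)
  if (!converged) {
    # boundary test: pin any component whose zero boundary improves the
    # restricted likelihood, then let EM finish
    ll_cur <- ll_at(sigma_r2, sigma_j2)
    pinned <- FALSE
    for (k in seq_along(sigma_r2)) {
      if (sigma_r2[k] > clamp) {
        trial <- sigma_r2; trial[k] <- clamp
        if (ll_at(trial, sigma_j2) > ll_cur) {
          sigma_r2 <- trial; pinned_r[k] <- TRUE
          ll_cur <- ll_at(sigma_r2, sigma_j2)
          pinned <- TRUE
        }
      }
    }
    for (j in seq_len(n_years)) {
      if (sigma_j2[j] > clamp) {
        trial <- sigma_j2; trial[j] <- clamp
        if (ll_at(sigma_r2, trial) > ll_cur) {
          sigma_j2 <- trial; pinned_j[j] <- TRUE
          ll_cur <- ll_at(sigma_r2, sigma_j2)
          pinned <- TRUE
        }
      }
    }
    if (pinned) em_phase(max_iter)
  }
  if (!converged) {
    # last resort: quasi-Newton-style polish on the log-variances
    par0 <- log(c(sigma_r2, sigma_j2))
    negll <- function(par) {
      v <- exp(par)
      -ll_at(v[seq_along(sigma_r2)], v[-seq_along(sigma_r2)])
    }
    op <- stats::optim(par0, negll, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-12))
    v <- exp(op$par)
    sigma_r2 <- pmax(v[seq_along(sigma_r2)], clamp)
    sigma_j2 <- pmax(v[-seq_along(sigma_r2)], clamp)
    converged <- op$convergence == 0
  }
  ms <- .mme_solve(y, W, ranef_idx, year_idx, sigma_r2, sigma_j2)
  ll <- .reml_loglik(ms, ranef_idx, year_idx, sigma_r2, sigma_j2, q)
  list(sigma_r2 = sigma_r2, sigma_j2 = sigma_j2,
       sol = ms$sol, Cinv = ms$Cinv, ehat = ms$ehat,
       p = p, ranef_idx = ranef_idx, loglik = ll, ll_trace = c(ll_trace, ll),
       converged = converged, n_iter = length(ll_trace),
       boundary_years = which(sigma_j2 <= clamp * 1.001))
}
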