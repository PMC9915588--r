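#' Select strong signals for data-driven covariance estimation
#'
#' Ranks features by the maximum absolute z-score (estimate / SE) over their
#' stacked time coefficients and returns the top fraction. Ties are broken
#' by feature id so the selected set does not depend on row order.
#'
#' @param fit A [fit_rhythm_models()] result.
#' @param top_frac Fraction of features to select, in (0, 1] (default 0.2).
#' @return Character vector of selected feature ids.
#' @export
select_strong_signals <- function(fit, top_frac = 0.2) {
  stopifnot(inherits(fit, "rhythm_fit"))
  if (!is.numeric(top_frac) || length(top_frac) != 1L || !is.finite(top_frac) ||
      top_frac <= 0 || top_frac > 1) {
    abort("`top_frac` must be in (0, 1].")
  }
  N <- length(fit$feature_ids)
  if (N < 10L) abort("Strong-signal selection needs at least 10 features.")
  eff <- stacked_effects(fit)
  z <- abs(eff$B) / pmax(eff$S, .Machine$double.eps)
  score <- apply(z, 1L, max)
  n_sel <- max(1L, ceiling(top_frac * N))
  ord <- order(-score, fit$feature_ids)
  fit$feature_ids[ord[seq_len(n_sel)]]
}

#' Data-driven prior covariance matrices from strong effects
#'
#' Computes the top principal directions of the column-centered strong-effect
#' matrix and returns, for each, the rank-1 outer product, plus the
#' rank-`n_pc` reconstruction covariance. Each matrix is normalized to unit
#' maximum diagonal (the scale grid carries the magnitude).
#'
#' @param effects Matrix of stacked time coefficients (strong features x p).
#' @param n_pc Number of principal components (default: number of spline
#'   knots upstream).
#' @return Named list of symmetric positive semidefinite p x p matrices.
#' @export
data_driven_covariances <- function(effects, n_pc) {
  effects <- as.matrix(effects)
  if (all(effects == 0)) abort("Strong effects are all zero; cannot derive covariances.")
  if (n_pc > ncol(effects) || n_pc > nrow(effects)) {
    abort("`n_pc` must not exceed the strong-effect matrix dimensions.")
  }
  ctr <- scale(effects, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = n_pc)
  out <- list()
  for (j in seq_len(n_pc)) {
    U <- tcrossprod(sv$v[, j])
    out[[paste0("pca_", j)]] <- normalize_cov(U)
  }
  V <- sv$v[, seq_len(n_pc), drop = FALSE]
  Ur <- V %*% diag(sv$d[seq_len(n_pc)]^2, n_pc) %*% t(V) / nrow(effects)
  out[[paste0("pca_rank", n_pc)]] <- normalize_cov(Ur)
  out
}

# Symmetrize, clip eigenvalues at zero, normalize max diagonal to 1.
normalize_cov <- function(U) {
  U <- (U + t(U)) / 2
  e <- eigen(U, symmetric = TRUE)
  U <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  U <- (U + t(U)) / 2
  dmax <- max(diag(U))
  if (dmax > 0) U <- U / dmax
  U
}

#' Variance scale grid for the shrinkage prior
#'
#' Geometric grid of prior variances, from `(min SE / 10)^2` up to at least
#' `(2 * max |estimate|)^2`, with ratio `grid_mult^2` between consecutive
#' values. Falls back to an effect-magnitude-based lower end if all standard
#' errors are zero.
#'
#' @param fit A `rhythm_fit`.
#' @param grid_mult Multiplier between consecutive grid standard deviations
#'   (default `sqrt(2)`).
#' @return Increasing numeric vector of variances.
#' @export
scale_grid <- function(fit, grid_mult = sqrt(2)) {
  stopifnot(inherits(fit, "rhythm_fit"))
  if (grid_mult <= 1) abort("`grid_mult` must be > 1.")
  eff <- stacked_effects(fit)
  absB <- abs(eff$B)
  hi <- (2 * max(absB))^2
  if (hi == 0) hi <- 1
  pos_se <- eff$S[eff$S > 0]
  lo <- if (length(pos_se)) {
    (min(pos_se) / 10)^2
  } else {
    nz <- absB[absB > 0]
    if (length(nz)) (min(nz) / 10)^2 else hi / 1e6
  }
  lo <- min(lo, hi / 2)
  ratio <- grid_mult^2
  n_step <- ceiling(log(hi / lo) / log(ratio))
  lo * ratio^(0:n_step)
}

# Assemble the full component table: every covariance matrix crossed with the
# scale grid, plus a single null (zero-covariance) component.
build_prior <- function(U_list, grid) {
  stopifnot(length(U_list) > 0)
  comps <- tidyr::expand_grid(U_name = names(U_list), omega = grid)
  comps <- dplyr::bind_rows(tibble(U_name = "null", omega = 1), comps)
  U_list <- c(list(null = matrix(0, nrow(U_list[[1L]]), ncol(U_list[[1L]]))),
              U_list)
  structure(
    list(U = U_list, components = comps, pi = NULL, grid = grid,
         loglik_trace = NULL),
    class = "shrinkage_prior"
  )
}

#' @export
print.shrinkage_prior <- function(x, ...) {
  cat(sprintf("<shrinkage_prior> %d covariance matrices x %d scales + null = %d components%s\n",
              length(x$U) - 1L, length(x$grid), nrow(x$components),
              if (is.null(x$pi)) " (weights not fitted)" else ""))
  invisible(x)
}

# Log density of N(b; 0, omega * U + V) for one feature/component.
mvn_logdens <- function(b, V, U, omega) {
  Sigma <- omega * U + V
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    diag(Sigma) <- diag(Sigma) + 1e-10 * max(diag(Sigma), 1)
    R <- chol(Sigma)
  }
  z <- backsolve(R, b, transpose = TRUE)
  -0.5 * length(b) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# Per-feature error covariance of the stacked coefficients: diag(SE) R
# diag(SE) with R the (optional) error-correlation matrix, else diagonal.
# A tiny jitter keeps the null component proper when some SEs are zero.
error_cov <- function(s, R, jitter) {
  V <- if (is.null(R)) diag(s^2, length(s)) else (s %o% s) * R
  diag(V) <- pmax(diag(V), jitter)
  V
}

# N x K matrix of per-feature per-component log-likelihoods.
component_logliks <- function(B, S, prior, R = NULL) {
  N <- nrow(B)
  K <- nrow(prior$components)
  jitter <- (1e-8 * max(1, max(abs(B))))^2
  L <- matrix(NA_real_, N, K)
  for (g in seq_len(N)) {
    V <- error_cov(S[g, ], R, jitter)
    for (k in seq_len(K)) {
      U <- prior$U[[prior$components$U_name[k]]]
      L[g, k] <- mvn_logdens(B[g, ], V, U, prior$components$omega[k])
    }
  }
  L
}

log_row_sum_exp <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Fit mixture weights of the shrinkage prior by EM
#'
#' Maximizes the marginal log-likelihood
#' `sum_g log sum_k pi_k N(b_g; 0, omega_k U_k + V_g)` over the simplex of
#' mixture weights, with component covariances fixed, by plain EM from a
#' uniform start. The log-likelihood is monotone nondecreasing across
#' iterations; the trace is stored on the returned prior.
#'
#' @param fit A `rhythm_fit` (supplies estimates and standard errors).
#' @param prior A `shrinkage_prior` (see [moderate_fits()] for the default
#'   construction).
#' @param tol Absolute log-likelihood gain below which EM stops (default
#'   1e-8).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param error_correlation `"full"` (default) uses the exact correlation of
#'   the stacked coefficients' OLS errors (all shifted models are refit on
#'   the same data); `"diagonal"` treats them as independent.
#' @return The prior with fitted weights `pi` and `loglik_trace`.
#' @export
fit_mixture_weights <- function(fit, prior, tol = 1e-8, max_iter = 2000,
                                error_correlation = c("full", "diagonal")) {
  error_correlation <- match.arg(error_correlation)
  eff <- stacked_effects(fit)
  R <- if (error_correlation == "full") fit$error_corr else NULL
  em_mixture_weights(eff$B, eff$S, prior, tol, max_iter, R = R)
}

em_mixture_weights <- function(B, S, prior, tol = 1e-8, max_iter = 2000,
                               R = NULL) {
  L <- component_logliks(B, S, prior, R = R)
  K <- ncol(L)
  pi_k <- rep(1 / K, K)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    A <- sweep(L, 2L, log(pmax(pi_k, 1e-300)), "+")
    ll_g <- log_row_sum_exp(A)
    trace <- c(trace, sum(ll_g))
    if (it > 1L && trace[it] - trace[it - 1L] < tol) break
    resp <- exp(A - ll_g)
    pi_k <- colMeans(resp)
  }
  prior$pi <- setNames(pi_k, paste0(prior$components$U_name, "_",
                                    signif(prior$components$omega, 3)))
  prior$loglik_trace <- trace
  prior$loglik_matrix <- L
  prior$error_corr <- R
  prior
}

#' Posterior distributions of the stacked time coefficients
#'
#' Under the fitted mixture prior, each feature's posterior is a mixture of
#' multivariate normals: component `(U, omega)` contributes with
#' responsibility proportional to `pi_k` times its marginal likelihood, with
#' conjugate posterior mean `omega U (omega U + V)^-1 b` and covariance
#' `omega U - omega U (omega U + V)^-1 omega U`. Intercept and covariate
#' coefficients are not moderated and pass through unchanged.
#'
#' @param fit A `rhythm_fit`.
#' @param prior A `shrinkage_prior` with fitted weights.
#' @return An object of class `rhythm_posterior`.
#' @export
compute_posteriors <- function(fit, prior) {
  stopifnot(inherits(fit, "rhythm_fit"), inherits(prior, "shrinkage_prior"))
  if (is.null(prior$pi)) abort("Fit the mixture weights first (fit_mixture_weights).")
  eff <- stacked_effects(fit)
  B <- eff$B; S <- eff$S
  N <- nrow(B); p <- ncol(B)
  L <- prior$loglik_matrix
  if (is.null(L) || nrow(L) != N) {
    L <- component_logliks(B, S, prior, R = prior$error_corr)
  }
  A <- sweep(L, 2L, log(pmax(prior$pi, 1e-300)), "+")
  resp <- exp(A - log_row_sum_exp(A))
  jitter <- (1e-8 * max(1, max(abs(B))))^2
  post_mean <- matrix(0, N, p, dimnames = dimnames(B))
  post_ex2 <- matrix(0, N, p)
  comp_store <- vector("list", N)
  keep_tol <- 1e-10
  for (g in seq_len(N)) {
    V <- error_cov(S[g, ], prior$error_corr, jitter)
    ks <- which(resp[g, ] > keep_tol)
    w <- resp[g, ks] / sum(resp[g, ks])
    mus <- vector("list", length(ks))
    Sigmas <- vector("list", length(ks))
    for (i in seq_along(ks)) {
      k <- ks[i]
      U <- prior$U[[prior$components$U_name[k]]]
      omega <- prior$components$omega[k]
      if (all(U == 0)) {
        mu <- numeric(p); Sg <- matrix(0, p, p)
      } else {
        P <- omega * U
        M <- P + V
        W <- tryCatch(P %*% chol2inv(chol(M)), error = function(e) {
          diag(M) <- diag(M) + 1e-10 * max(diag(M), 1)
          P %*% chol2inv(chol(M))
        })
        mu <- drop(W %*% B[g, ])
        Sg <- P - W %*% P
        Sg <- (Sg + t(Sg)) / 2
        ev <- eigen(Sg, symmetric = TRUE)
        Sg <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
      }
      mus[[i]] <- mu
      Sigmas[[i]] <- Sg
      post_mean[g, ] <- post_mean[g, ] + w[i] * mu
      post_ex2[g, ] <- post_ex2[g, ] + w[i] * (diag(Sg) + mu^2)
    }
    comp_store[[g]] <- list(w = w, mu = mus, Sigma = Sigmas)
  }
  post_sd <- sqrt(pmax(post_ex2 - post_mean^2, 0))
  dimnames(post_sd) <- dimnames(B)
  structure(
    list(fit = fit, prior = prior, raw = B, raw_se = S,
         post_mean = post_mean, post_sd = post_sd,
         responsibilities = resp, components = comp_store),
    class = "rhythm_posterior"
  )
}

#' @export
print.rhythm_posterior <- function(x, ...) {
  cat(sprintf("<rhythm_posterior> %d features, %d coefficient dims, %d prior components\n",
              nrow(x$post_mean), ncol(x$post_mean), nrow(x$prior$components)))
  invisible(x)
}

#' Moderate a rhythm fit with an empirical-Bayes multivariate prior
#'
#' One-call wrapper around the shrinkage workflow: selects strong signals,
#' derives data-driven covariance matrices by PCA (number of components =
#' number of spline knots by default), adds an identity component and a null
#' component, builds the scale grid, fits the mixture weights by EM, and
#' computes posterior means and SDs of every feature's time coefficients.
#'
#' @inheritParams select_strong_signals
#' @inheritParams scale_grid
#' @param n_pc Number of principal components for the data-driven
#'   covariances (default: the number of spline knots, or the basis
#'   dimension for cosinor).
#' @param include_canonical Also add rank-1 per-coordinate covariance
#'   matrices (default `FALSE`).
#' @param ridge Regularization of the data-driven covariance matrices:
#'   each is replaced by `(1 - ridge) * U + ridge * I` (default 0.1). The
#'   PCA matrices are (near) rank deficient; without the ridge the
#'   posterior treats their estimated column space as exact and becomes
#'   overconfident in directions the strong signals happen not to span.
#' @param tol,max_iter EM stopping controls.
#' @param error_correlation `"full"` (default) models the exact correlation
#'   of the stacked coefficients' OLS errors in the likelihood and
#'   posteriors; `"diagonal"` treats coefficient errors as independent.
#' @return A `rhythm_posterior`.
#' @export
moderate_fits <- function(fit, top_frac = 0.2, n_pc = NULL,
                          grid_mult = sqrt(2), include_canonical = FALSE,
                          ridge = 0.1, tol = 1e-8, max_iter = 2000,
                          error_correlation = c("full", "diagonal")) {
  error_correlation <- match.arg(error_correlation)
  if (ridge < 0 || ridge >= 1) abort("`ridge` must be in [0, 1).")
  stopifnot(inherits(fit, "rhythm_fit"))
  eff <- stacked_effects(fit)
  p <- ncol(eff$B)
  if (is.null(n_pc)) {
    n_pc <- if (fit$method == "periodic_spline") fit$n_knots else fit$basis_dim
  }
  strong <- select_strong_signals(fit, top_frac = top_frac)
  n_pc <- min(n_pc, p, length(strong))
  U_list <- data_driven_covariances(eff$B[strong, , drop = FALSE], n_pc)
  if (ridge > 0) {
    U_list <- lapply(U_list, function(U) (1 - ridge) * U + ridge * diag(p))
  }
  U_list$identity <- diag(p)
  if (include_canonical) {
    for (j in seq_len(p)) {
      E <- matrix(0, p, p); E[j, j] <- 1
      U_list[[paste0("coord_", j)]] <- E
    }
  }
  prior <- build_prior(U_list, scale_grid(fit, grid_mult = grid_mult))
  prior <- fit_mixture_weights(fit, prior, tol = tol, max_iter = max_iter,
                               error_correlation = error_correlation)
  compute_posteriors(fit, prior)
}

#' Posterior-mean version of a rhythm fit
#'
#' Returns a `rhythm_fit` whose time coefficients are replaced by their
#' posterior means (intercepts and covariate coefficients unchanged), so
#' curve evaluation and rhythm statistics work on the moderated fit.
#'
#' @param post A `rhythm_posterior`.
#' @return A `rhythm_fit`.
#' @export
posterior_fit <- function(post) {
  stopifnot(inherits(post, "rhythm_posterior"))
  fit <- post$fit
  tc <- time_cols(fit)
  d <- fit$basis_dim
  for (k in seq_len(fit$n_shifts)) {
    fit$coef[[k]][, tc] <- post$post_mean[, (k - 1L) * d + seq_len(d)]
    fit$se[[k]][, tc] <- post$post_sd[, (k - 1L) * d + seq_len(d)]
  }
  fit
}

#' Draw samples from the coefficient posteriors
#'
#' For each feature and draw, samples a mixture component from the feature's
#' responsibilities and then a multivariate-normal vector from that
#' component's conjugate posterior. Reproducible under a fixed seed.
#'
#' @param post A `rhythm_posterior`.
#' @param n_samples Number of draws (default 200).
#' @param seed Integer seed (optional).
#' @return Array `features x n_samples x p` of time-coefficient draws.
#' @export
sample_posterior <- function(post, n_samples = 200, seed = NULL) {
  stopifnot(inherits(post, "rhythm_posterior"))
  if (n_samples < 1) abort("`n_samples` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(post$post_mean)
  p <- ncol(post$post_mean)
  draws <- array(0, dim = c(N, n_samples, p),
                 dimnames = list(rownames(post$post_mean), NULL,
                                 colnames(post$post_mean)))
  for (g in seq_len(N)) {
    cs <- post$components[[g]]
    ki <- if (length(cs$w) == 1L) rep(1L, n_samples) else {
      sample.int(length(cs$w), n_samples, replace = TRUE, prob = cs$w)
    }
    chols <- lapply(cs$Sigma, function(Sg) {
      if (all(Sg == 0)) NULL else chol(Sg + diag(1e-12 * max(diag(Sg), 1e-300), p))
    })
    Z <- matrix(rnorm(n_samples * p), n_samples, p)
    for (s in seq_len(n_samples)) {
      k <- ki[s]
      draws[g, s, ] <- if (is.null(chols[[k]])) cs$mu[[k]] else {
        cs$mu[[k]] + drop(Z[s, ] %*% chols[[k]])
      }
    }
  }
  draws
}

#' Tidy posterior coefficient summaries
#'
#' @param x A `rhythm_posterior`.
#' @param ... Unused.
#' @return Tibble with `feature_id`, `term`, `raw_estimate`, `raw_se`,
#'   `posterior_mean`, `posterior_sd`.
#' @export
tidy.rhythm_posterior <- function(x, ...) {
  tibble(
    feature_id = rep(rownames(x$raw), times = ncol(x$raw)),
    term = rep(colnames(x$raw), each = nrow(x$raw)),
    raw_estimate = as.vector(x$raw),
    raw_se = as.vector(x$raw_se),
    posterior_mean = as.vector(x$post_mean),
    posterior_sd = as.vector(x$post_sd)
  )
}

#' One-row summary of a fitted shrinkage posterior
#'
#' @param x A `rhythm_posterior`.
#' @param ... Unused.
#' @return A one-row tibble with the final marginal log-likelihood, number
#'   of EM iterations, component count, and estimated null weight.
#' @export
glance.rhythm_posterior <- function(x, ...) {
  trace <- x$prior$loglik_trace
  null_idx <- which(x$prior$components$U_name == "null")
  tibble(
    n_features = nrow(x$post_mean),
    n_components = nrow(x$prior$components),
    em_iterations = length(trace),
    log_likelihood = trace[length(trace)],
    null_weight = sum(x$prior$pi[null_idx])
  )
}
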