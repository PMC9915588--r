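#' Fit knot-shifted periodic linear models for every feature
#'
#' For each feature (row of `data`), fits `n_shifts` ordinary-least-squares
#' linear models whose time terms come from a periodic cubic spline basis
#' with shifted knots (or a single cosinor model). Per-coefficient standard
#' errors come from `s^2 * diag((X'X)^-1)`. The stacked time coefficients
#' and standard errors across all shifted models feed the empirical-Bayes
#' shrinkage step ([moderate_fits()]).
#'
#' @param data Wide expression table (first column `feature_id`, one numeric
#'   column per sample; log-scale values) or a matrix with feature rownames.
#' @param metadata Data frame with `sample_id`, `time` (hours), and optional
#'   covariate columns; rows are matched to `data`'s sample columns by id.
#' @param period Rhythm period in hours (default 24).
#' @param method `"periodic_spline"` (default) or `"cosinor"`.
#' @param n_knots Internal spline knots (default 3).
#' @param n_shifts Number of knot-shifted models `m` (default 3; forced to 1
#'   for cosinor, whose basis does not depend on knots).
#' @param covariates Optional character vector of covariate columns.
#' @param moderate_var If `TRUE`, apply empirical-Bayes variance moderation
#'   ([moderate_variances()]) to the residual variances before computing
#'   standard errors.
#' @return An object of class `rhythm_fit`.
#' @export
fit_rhythm_models <- function(data, metadata, period = 24,
                              method = c("periodic_spline", "cosinor"),
                              n_knots = 3, n_shifts = 3, covariates = NULL,
                              moderate_var = FALSE) {
  method <- match.arg(method)
  Y <- as_feature_matrix(data, "data")
  if (any(!is.finite(Y))) abort("Expression values must be finite.")
  metadata <- check_metadata(metadata, colnames(Y))
  if (method == "cosinor") n_shifts <- 1L
  shifts <- if (method == "cosinor") 0 else knot_shifts(n_shifts, n_knots, period)
  bases <- lapply(shifts, function(d) {
    time_basis(method, period = period, n_knots = n_knots, shift = d)
  })
  basis_dim <- bases[[1L]]$dim
  designs <- lapply(bases, build_design, metadata = metadata,
                    covariates = covariates)
  q <- ncol(designs[[1L]])
  df_resid <- ncol(Y) - q
  if (df_resid < 1L) {
    abort(sprintf("Need more samples than design columns (+1): %d samples, %d columns.",
                  ncol(Y), q))
  }
  N <- nrow(Y)
  coefs <- ses <- vector("list", n_shifts)
  sigma2 <- matrix(NA_real_, N, n_shifts)
  for (k in seq_len(n_shifts)) {
    X <- designs[[k]]
    qrX <- qr(X)
    bhat <- t(qr.coef(qrX, t(Y)))
    resid <- Y - bhat %*% t(X)
    s2 <- rowSums(resid^2) / df_resid
    low <- s2 < 1e-12
    if (any(low)) {
      warn(sprintf("%d feature(s) with near-zero residual variance; floored at 1e-12.",
                   sum(low)))
      s2[low] <- 1e-12
    }
    xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
    se <- sqrt(outer(s2, xtx_inv_diag))
    dimnames(bhat) <- dimnames(se) <- list(rownames(Y), colnames(X))
    if (any(!is.finite(bhat))) {
      bad <- rownames(Y)[which(!is.finite(rowSums(bhat)))[1L]]
      abort(sprintf("Non-finite coefficients for feature '%s' (shift %d).", bad, k))
    }
    coefs[[k]] <- bhat
    ses[[k]] <- se
    sigma2[, k] <- s2
  }
  fit <- structure(
    list(
      feature_ids = rownames(Y), sample_ids = colnames(Y),
      time = metadata$time, mean_expr = rowMeans(Y),
      method = method, period = period, n_knots = n_knots,
      n_shifts = n_shifts, basis_dim = basis_dim, covariates = covariates,
      bases = bases, designs = designs, coef = coefs, se = ses,
      sigma2 = sigma2, df_resid = df_resid, moderated = FALSE
    ),
    class = "rhythm_fit"
  )
  fit$error_corr <- coef_error_correlation(fit)
  if (moderate_var) fit <- moderate_variances(fit)
  fit
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf(
    "<rhythm_fit> %d features, %d samples, %s basis (dim %d), %d shifted model(s), period %g h%s\n",
    length(x$feature_ids), length(x$sample_ids), x$method, x$basis_dim,
    x$n_shifts, x$period, if (x$moderated) ", variance-moderated" else ""
  ))
  invisible(x)
}

# Indices of time-basis columns within a single model's coefficient matrix.
time_cols <- function(fit) 1L + seq_len(fit$basis_dim)

# Exact correlation matrix of the stacked time-coefficient OLS errors. All
# shifted models are refit on the same response, so their coefficient errors
# are deterministic linear maps of one residual vector:
# cov(bhat_j, bhat_k) = sigma^2 A_j A_k' with A_k = (X_k'X_k)^-1 X_k'.
# The sigma^2 scale cancels in the correlation, which is shared by all
# features and lets the shrinkage likelihood account for cross-model (and
# within-model) error dependence.
coef_error_correlation <- function(fit) {
  tc <- time_cols(fit)
  A <- lapply(fit$designs, function(X) {
    (chol2inv(chol(crossprod(X))) %*% t(X))[tc, , drop = FALSE]
  })
  m <- fit$n_shifts
  d <- fit$basis_dim
  C <- matrix(0, m * d, m * d)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      C[(j - 1L) * d + seq_len(d), (k - 1L) * d + seq_len(d)] <-
        tcrossprod(A[[j]], A[[k]])
    }
  }
  stats::cov2cor(C)
}

# Stacked time coefficients (N x p) and their SEs across all shifted models.
stacked_effects <- function(fit) {
  tc <- time_cols(fit)
  B <- do.call(cbind, lapply(fit$coef, function(cf) cf[, tc, drop = FALSE]))
  S <- do.call(cbind, lapply(fit$se, function(se) se[, tc, drop = FALSE]))
  labels <- unlist(lapply(seq_len(fit$n_shifts), function(k) {
    paste0("shift", k, "_", colnames(fit$coef[[k]])[tc])
  }))
  colnames(B) <- colnames(S) <- labels
  rownames(B) <- rownames(S) <- fit$feature_ids
  list(B = B, S = S)
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks each feature's residual variance toward a prior variance
#' estimated from all features, replacing `s^2` by the posterior
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`. The prior degrees of
#' freedom `d0` and prior variance `s0^2` are obtained by matching the
#' first two moments of the observed `s^2` to a scaled
#' inverse-chi-squared sampling model (marginally, `s^2 ~ s0^2 F(d, d0)`).
#' Standard errors are rescaled by `s_tilde / s`. With `trend = TRUE` the
#' prior variance follows a log-linear trend on average expression.
#'
#' @param fit A [fit_rhythm_models()] result.
#' @param trend Allow the prior variance to depend log-linearly on average
#'   expression (default `FALSE`: a single global prior).
#' @return The fit with moderated variances and standard errors.
#' @export
moderate_variances <- function(fit, trend = FALSE) {
  stopifnot(inherits(fit, "rhythm_fit"))
  N <- length(fit$feature_ids)
  if (N < 3L) abort("Variance moderation needs at least 3 features.")
  if (N < 20L) {
    warn("Fewer than 20 features: variance-moderation hyperparameters may be unstable.")
  }
  d <- fit$df_resid
  for (k in seq_len(fit$n_shifts)) {
    s2 <- fit$sigma2[, k]
    rel <- rep(1, N)
    if (trend) {
      tr <- stats::lm.fit(cbind(1, fit$mean_expr), log(s2))
      rel <- exp(tr$fitted.values - mean(tr$fitted.values))
    }
    z <- s2 / rel
    hp <- fit_inverse_chisq_prior(z, d)
    s2_new <- (hp$d0 * hp$s0_sq * rel + d * s2) / (hp$d0 + d)
    if (!is.finite(hp$d0)) s2_new <- hp$s0_sq * rel
    fit$se[[k]] <- fit$se[[k]] * sqrt(s2_new / s2)
    fit$sigma2[, k] <- s2_new
  }
  fit$moderated <- TRUE
  fit
}

# Moment-matching estimate of (d0, s0^2) for the scaled inverse-chi-squared
# prior on residual variances: marginally s^2 ~ s0^2 F(d, d0), so
# E[s^2] = s0^2 d0/(d0-2) and var/mean^2 = r = 2(d + d0 - 2)/(d (d0 - 4)).
# r*d <= 2 means less spread than an infinite-d0 prior predicts: complete
# pooling (d0 = Inf, s0^2 = mean).
fit_inverse_chisq_prior <- function(s2, d) {
  m1 <- mean(s2)
  r <- var(s2) / m1^2
  if (!is.finite(r) || r * d <= 2 + 1e-12) {
    return(list(d0 = Inf, s0_sq = m1))
  }
  d0 <- (4 * r * d - 4) / (r * d - 2)
  list(d0 = d0, s0_sq = m1 * (d0 - 2) / d0)
}

#' Evaluate one shifted model's fitted curve
#'
#' Predicted expectation at times `t` for a single feature and shift, i.e.
#' the product of the design row at `t` with the model's coefficients.
#' Covariates are held at reference values (indicators 0, numeric
#' covariates at their observed mean) unless supplied.
#'
#' @param fit A `rhythm_fit`.
#' @param t Times in hours.
#' @param feature Feature id or index.
#' @param shift Which shifted model (default 1).
#' @param covariate_values Optional named list of covariate values.
#' @return Numeric vector of predictions, one per time.
#' @export
evaluate_fit <- function(fit, t, feature, shift = 1L, covariate_values = NULL) {
  stopifnot(inherits(fit, "rhythm_fit"))
  g <- if (is.character(feature)) match(feature, fit$feature_ids) else feature
  if (is.na(g)) abort(sprintf("Unknown feature '%s'.", feature))
  beta <- fit$coef[[shift]][g, ]
  Xn <- prediction_design(fit, t, shift, covariate_values)
  drop(Xn %*% beta)
}

prediction_design <- function(fit, t, shift, covariate_values = NULL) {
  Xt <- cbind(1, eval_basis(fit$bases[[shift]], t))
  q <- ncol(fit$coef[[shift]])
  extra <- q - ncol(Xt)
  if (extra > 0L) {
    labels <- colnames(fit$coef[[shift]])[(ncol(Xt) + 1L):q]
    vals <- numeric(extra)
    numeric_cov <- intersect(fit$covariates, labels)
    for (cv in numeric_cov) {
      # numeric covariates default to their design-matrix mean
      vals[match(cv, labels)] <- mean(fit$designs[[shift]][, cv])
    }
    if (!is.null(covariate_values)) {
      for (nm in names(covariate_values)) {
        if (nm %in% labels) {
          vals[match(nm, labels)] <- covariate_values[[nm]]
        } else if (nm %in% fit$covariates && !nm %in% labels) {
          # categorical covariate given by original name + level
          abort(sprintf("Supply categorical covariates as indicator columns (e.g. '%s_<level>').", nm))
        }
      }
    }
    Xt <- cbind(Xt, matrix(rep(vals, each = length(t)), nrow = length(t)))
  }
  Xt
}

#' Average the shifted models' fitted curves
#'
#' The overall raw fit of a feature is the pointwise mean of its `m`
#' shifted models' predictions.
#'
#' @inheritParams evaluate_fit
#' @param features Feature ids or indices (default all).
#' @return A matrix (features x times) of averaged predictions.
#' @export
average_fits <- function(fit, t, features = NULL, covariate_values = NULL) {
  stopifnot(inherits(fit, "rhythm_fit"))
  idx <- resolve_features(fit, features)
  acc <- matrix(0, length(idx), length(t))
  for (k in seq_len(fit$n_shifts)) {
    Xn <- prediction_design(fit, t, k, covariate_values)
    acc <- acc + fit$coef[[k]][idx, , drop = FALSE] %*% t(Xn)
  }
  out <- acc / fit$n_shifts
  rownames(out) <- fit$feature_ids[idx]
  out
}

resolve_features <- function(fit, features) {
  if (is.null(features)) return(seq_along(fit$feature_ids))
  idx <- if (is.character(features)) match(features, fit$feature_ids) else features
  if (any(is.na(idx))) abort("Unknown feature id(s).")
  idx
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-coefficient estimates of a rhythm fit
#'
#' @param x A `rhythm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `shift`, `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.rhythm_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_shifts), function(k) {
    cf <- x$coef[[k]]
    se <- x$se[[k]]
    tibble(
      feature_id = rep(rownames(cf), times = ncol(cf)),
      shift = k,
      term = rep(colnames(cf), each = nrow(cf)),
      estimate = as.vector(cf),
      std.error = as.vector(se)
    )
  })
}

#' One-row summary of a rhythm fit
#'
#' @param x A `rhythm_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.rhythm_fit <- function(x, ...) {
  tibble(
    n_features = length(x$feature_ids), n_samples = length(x$sample_ids),
    method = x$method, n_shifts = x$n_shifts, basis_dim = x$basis_dim,
    period = x$period, df_resid = x$df_resid, moderated = x$moderated
  )
}
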