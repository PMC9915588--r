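# Shared fixtures and independent oracles, built in code at test time.

# Sample metadata for S samples spaced `by` hours apart.
make_metadata <- function(n_samples, by = 2) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    time = (seq_len(n_samples) - 1) * by
  )
}

# Matrix of pure sinusoids (one row per parameter set) sampled at `time`.
make_sinusoid_matrix <- function(time, mesor, amp_half, phase, period = 24,
                                 noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(mesor)
  Y <- matrix(NA_real_, n, length(time),
              dimnames = list(paste0("g", seq_len(n)),
                              sprintf("s%02d", seq_along(time))))
  for (i in seq_len(n)) {
    Y[i, ] <- mesor[i] + amp_half[i] * cos(2 * pi * (time - phase[i]) / period)
  }
  if (noise_sd > 0) Y <- Y + matrix(rnorm(length(Y), 0, noise_sd), nrow(Y))
  Y
}

# Independent periodic cubic B-spline oracle: Cox-de Boor recursion coded
# from the textbook definition (no splines:: calls), evaluated on a
# period-extended knot vector and folded modulo the number of circle knots.
deboor_bspline <- function(x, knots, j, degree) {
  if (degree == 0) {
    return(as.numeric(x >= knots[j] & x < knots[j + 1]))
  }
  d1 <- knots[j + degree] - knots[j]
  d2 <- knots[j + degree + 1] - knots[j + 1]
  a <- if (d1 > 0) (x - knots[j]) / d1 * deboor_bspline(x, knots, j, degree - 1) else 0
  b <- if (d2 > 0) (knots[j + degree + 1] - x) / d2 *
    deboor_bspline(x, knots, j + 1, degree - 1) else 0
  a + b
}

oracle_periodic_spline <- function(t, period, n_knots, shift = 0) {
  K <- n_knots + 1L
  x <- (t - shift) %% period
  knots <- ((-4L):(K + 4L)) * period / K
  n_basis <- length(knots) - 4L
  B <- sapply(seq_len(n_basis), function(j) deboor_bspline(x, knots, j, 3L))
  if (is.null(dim(B))) B <- matrix(B, nrow = 1L)
  P <- matrix(0, length(x), K)
  for (j in seq_len(n_basis)) {
    jj <- ((j - 1L) %% K) + 1L
    P[, jj] <- P[, jj] + B[, j]
  }
  P[, seq_len(n_knots), drop = FALSE]
}

# Minimal hand-built fit object for shrinkage oracles on constructed
# estimates/SEs (p = n_shifts * basis_dim stacked coefficients).
fake_fit <- function(B, S, n_shifts = 1L, error_corr = NULL) {
  B <- as.matrix(B); S <- as.matrix(S)
  p <- ncol(B)
  stopifnot(p %% n_shifts == 0)
  d <- p %/% n_shifts
  ids <- paste0("f", seq_len(nrow(B)))
  coefs <- ses <- vector("list", n_shifts)
  for (k in seq_len(n_shifts)) {
    cols <- (k - 1L) * d + seq_len(d)
    coefs[[k]] <- cbind(intercept = 0, B[, cols, drop = FALSE])
    ses[[k]] <- cbind(intercept = 0, S[, cols, drop = FALSE])
    rownames(coefs[[k]]) <- rownames(ses[[k]]) <- ids
  }
  structure(
    list(feature_ids = ids, sample_ids = character(), time = numeric(),
         mean_expr = rep(0, nrow(B)), method = "periodic_spline",
         period = 24, n_knots = d, n_shifts = n_shifts, basis_dim = d,
         covariates = NULL, bases = NULL, designs = NULL,
         coef = coefs, se = ses, sigma2 = matrix(1, nrow(B), n_shifts),
         df_resid = 10, moderated = FALSE,
         error_corr = error_corr %||% diag(p)),
    class = "rhythm_fit"
  )
}

# Prior with explicitly chosen covariance components (bypasses the
# data-driven construction); `U_list` excludes the null, which build_prior
# adds.
make_prior <- function(U_list, grid = 1) {
  rhythmeb:::build_prior(U_list, grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
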