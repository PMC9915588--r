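#' Periodic time basis
#'
#' Describes the time terms of the per-feature linear model: either a
#' periodic cubic spline with `n_knots` internal knots (knot spacing
#' `period / (n_knots + 1)`, shifted by `shift`) or a cosinor basis
#' (cosine and sine at the fundamental frequency). Basis functions are
#' exactly periodic in `period` by construction.
#'
#' @param kind `"periodic_spline"` or `"cosinor"`.
#' @param period Period in hours (default 24).
#' @param n_knots Number of internal spline knots (default 3; spline only).
#' @param shift Knot shift in hours, in `[0, period)` (spline only).
#' @return An object of class `time_basis`.
#' @export
time_basis <- function(kind = c("periodic_spline", "cosinor"), period = 24,
                       n_knots = 3, shift = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0) {
    abort("`period` must be a single positive number (hours).")
  }
  if (kind == "periodic_spline") {
    if (n_knots < 2) {
      abort("`n_knots` must be >= 2 for a periodic cubic spline basis.")
    }
    if (shift < 0 || shift >= period) {
      abort("`shift` must lie in [0, period).")
    }
  } else {
    n_knots <- NA_integer_
    shift <- 0
  }
  structure(
    list(kind = kind, period = period, n_knots = n_knots, shift = shift,
         dim = if (kind == "cosinor") 2L else as.integer(n_knots)),
    class = "time_basis"
  )
}

#' @export
print.time_basis <- function(x, ...) {
  cat(sprintf("<time_basis> %s, period %g h", x$kind, x$period))
  if (x$kind == "periodic_spline") {
    cat(sprintf(", %d knots, shift %g h", x$n_knots, x$shift))
  }
  cat(sprintf(", %d columns\n", x$dim))
  invisible(x)
}

#' Knot shifts for a set of shifted spline models
#'
#' For `m` shifted models the shift of model `k` is
#' `(k - 1) * period / (m * (n_knots + 1))`, stepping evenly through one
#' inter-knot gap; the first model is always unshifted.
#'
#' @param m Number of shifted models (>= 1).
#' @param n_knots Number of internal spline knots.
#' @param period Period in hours.
#' @return Numeric vector of `m` shifts in hours.
#' @export
#' @examples
#' knot_shifts(3, 3, 24) # 0 2 4
knot_shifts <- function(m, n_knots, period) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    abort("`m` must be a positive integer.")
  }
  if (n_knots < 1) abort("`n_knots` must be >= 1.")
  if (period <= 0) abort("`period` must be positive.")
  (seq_len(m) - 1) * period / (m * (n_knots + 1))
}

#' Evaluate a periodic time basis
#'
#' Returns the design columns of the basis at times `t` (hours). Times are
#' reduced modulo the period first, so samples a whole period apart are
#' treated as replicates. For the spline kind the columns are periodic cubic
#' B-splines built on a circularly wrapped, equally spaced knot vector; for
#' the cosinor kind they are `cos(theta)` and `sin(theta)` with
#' `theta = 2 * pi * t / period`.
#'
#' @param basis A [time_basis()].
#' @param t Numeric vector of times in hours.
#' @return A numeric matrix with `length(t)` rows and `basis$dim` columns.
#' @export
eval_basis <- function(basis, t) {
  stopifnot(inherits(basis, "time_basis"))
  if (any(!is.finite(t))) abort("Times must be finite.")
  if (basis$kind == "cosinor") {
    theta <- 2 * pi * t / basis$period
    out <- cbind(cos_t = cos(theta), sin_t = sin(theta))
    return(out)
  }
  periodic_spline_basis(t, basis$period, basis$n_knots, basis$shift)
}

# Periodic cubic B-splines: n_knots internal knots plus the period boundary
# give K = n_knots + 1 equally spaced knots on the circle. Ordinary cubic
# B-splines are evaluated on a period-extended knot vector and folded modulo
# K, which enforces exact periodicity. The folded functions sum to one, so
# the last column is dropped; together with an intercept the returned
# n_knots columns span the full (K-dimensional) periodic spline space.
periodic_spline_basis <- function(t, period, n_knots, shift = 0) {
  K <- n_knots + 1L
  x <- (t - shift) %% period
  knots <- ((-4L):(K + 4L)) * period / K
  B <- splines::splineDesign(knots, x, ord = 4L, outer.ok = TRUE)
  P <- matrix(0, length(x), K)
  for (j in seq_len(ncol(B))) {
    jj <- ((j - 1L) %% K) + 1L
    P[, jj] <- P[, jj] + B[, j]
  }
  P <- P[, seq_len(n_knots), drop = FALSE]
  colnames(P) <- paste0("spline_", seq_len(n_knots))
  P
}

#' Build a regression design matrix
#'
#' Assembles intercept, time-basis columns, and (optionally) covariate
#' columns from sample metadata. Categorical covariates use treatment
#' coding with the first sorted level as reference.
#'
#' @param metadata Data frame with columns `sample_id`, `time` (hours), and
#'   any covariate columns.
#' @param basis A [time_basis()].
#' @param covariates Character vector of covariate column names (optional).
#' @return A numeric design matrix (samples x columns) with labelled
#'   columns; the first column is the intercept.
#' @export
build_design <- function(metadata, basis, covariates = NULL) {
  metadata <- check_metadata(metadata)
  X <- cbind(intercept = rep(1, nrow(metadata)), eval_basis(basis, metadata$time))
  if (length(covariates)) {
    missing <- setdiff(covariates, names(metadata))
    if (length(missing)) {
      abort(sprintf("Covariate column(s) not in metadata: %s",
                    paste(missing, collapse = ", ")))
    }
    for (cv in covariates) {
      v <- metadata[[cv]]
      if (is.numeric(v)) {
        X <- cbind(X, setNames(data.frame(v), cv))
        colnames(X)[ncol(X)] <- cv
        X <- as.matrix(X)
      } else {
        lev <- sort(unique(as.character(v)))
        if (length(lev) < 2L) {
          abort(sprintf("Covariate '%s' has fewer than 2 levels.", cv))
        }
        for (l in lev[-1L]) {
          X <- cbind(X, as.numeric(as.character(v) == l))
          colnames(X)[ncol(X)] <- paste0(cv, "_", l)
        }
      }
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  X
}
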