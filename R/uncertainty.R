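#' Rhythm statistics of posterior coefficient draws
#'
#' Converts each posterior coefficient draw into the corresponding averaged
#' fitted curve (same shift-averaging as the raw fits, intercepts and
#' covariate coefficients held at their unmoderated values) and scores it
#' with the rhythm statistics.
#'
#' @param post A `rhythm_posterior`.
#' @param draws Array from [sample_posterior()] (features x draws x p). If
#'   `NULL`, draws are generated with `n_samples` and `seed`.
#' @param n_samples,seed Used only when `draws` is `NULL`.
#' @param grid_n Curve grid resolution per period (default 256).
#' @return An object of class `statistic_draws`: per-statistic matrices
#'   (features x draws) plus the period.
#' @export
statistics_from_draws <- function(post, draws = NULL, n_samples = 200,
                                  seed = NULL, grid_n = 256) {
  stopifnot(inherits(post, "rhythm_posterior"))
  if (is.null(draws)) draws <- sample_posterior(post, n_samples, seed = seed)
  fit <- post$fit
  grid <- curve_grid(fit$period, grid_n)
  d <- fit$basis_dim
  m <- fit$n_shifts
  tc <- time_cols(fit)
  # G x p stacked grid basis across shifts, and the fixed (non-time) part
  Gstack <- matrix(0, length(grid), m * d)
  N <- dim(draws)[1L]
  fixed <- matrix(0, N, length(grid))
  for (k in seq_len(m)) {
    Xg <- prediction_design(fit, grid, k)
    Gstack[, (k - 1L) * d + seq_len(d)] <- Xg[, tc, drop = FALSE]
    cf_fixed <- fit$coef[[k]][, -tc, drop = FALSE]
    fixed <- fixed + cf_fixed %*% t(Xg[, -tc, drop = FALSE])
  }
  n_draw <- dim(draws)[2L]
  stat_names <- c("mesor", "peak", "peak_phase", "trough", "trough_phase",
                  "ptt_amplitude", "rms_amplitude")
  out <- lapply(stat_names, function(s) {
    matrix(NA_real_, N, n_draw, dimnames = list(fit$feature_ids, NULL))
  })
  names(out) <- stat_names
  for (g in seq_len(N)) {
    curves <- draws[g, , , drop = FALSE]
    dim(curves) <- dim(draws)[2:3]
    curves <- curves %*% t(Gstack) / m
    curves <- sweep(curves, 2L, fixed[g, ] / m, "+")
    st <- curve_statistics_matrix(curves, fit$period)
    for (s in stat_names) out[[s]][g, ] <- st[[s]]
  }
  structure(c(out, list(period = fit$period, n_samples = n_draw)),
            class = "statistic_draws")
}

#' @export
print.statistic_draws <- function(x, ...) {
  cat(sprintf("<statistic_draws> %d features x %d draws, period %g h\n",
              nrow(x$mesor), x$n_samples, x$period))
  invisible(x)
}

#' Sign-flip amplitude draws far from the consensus phase
#'
#' Amplitude draws are nonnegative by construction, so their credible
#' intervals could never span zero. For each feature this computes the
#' circular mean peak phase over draws, weighted by (absolute)
#' peak-to-trough amplitude, and negates both amplitude statistics of any
#' draw whose peak phase is strictly more than a quarter period away from
#' that mean. If the circular mean is undefined (near-zero resultant) the
#' draws are left positive with a warning.
#'
#' @param stat_draws A [statistics_from_draws()] result.
#' @return A list with matrices `ptt_amplitude` and `rms_amplitude`
#'   (signed), the per-feature `mean_peak_phase`, and the logical flip
#'   matrix.
#' @export
signed_amplitudes <- function(stat_draws) {
  stopifnot(inherits(stat_draws, "statistic_draws"))
  period <- stat_draws$period
  ph <- stat_draws$peak_phase
  amp <- stat_draws$ptt_amplitude
  N <- nrow(ph)
  mean_phase <- rep(NA_real_, N)
  flip <- matrix(FALSE, N, ncol(ph))
  undefined <- 0L
  for (g in seq_len(N)) {
    cm <- tryCatch(
      circular_mean_phase(ph[g, ], weights = abs(amp[g, ]), period = period),
      error = function(e) NA_real_
    )
    mean_phase[g] <- cm
    if (is.na(cm)) {
      undefined <- undefined + 1L
      next
    }
    flip[g, ] <- circular_distance(ph[g, ], cm, period) > period / 4
  }
  if (undefined > 0L) {
    warn(sprintf(
      "Circular mean phase undefined for %d feature(s); their amplitude draws were left positive.",
      undefined
    ))
  }
  sgn <- 1 - 2 * flip
  list(
    ptt_amplitude = stat_draws$ptt_amplitude * sgn,
    rms_amplitude = stat_draws$rms_amplitude * sgn,
    mean_peak_phase = setNames(mean_phase, rownames(ph)),
    flipped = flip
  )
}

#' Credible interval from posterior samples
#'
#' Equal-tailed intervals use the `(1 - level) / 2` and `1 - (1 - level) / 2`
#' empirical quantiles with linear interpolation (R's default type-7
#' quantile). Highest-density intervals take the narrowest window of sorted
#' samples containing a `level` fraction of them.
#'
#' @param samples Numeric vector of posterior samples.
#' @param level Credible level in (0, 1) (default 0.90).
#' @param method `"equal_tailed"` (default) or `"highest_density"`.
#' @return A one-row tibble: `lower`, `upper`, `level`, `method`.
#' @export
credible_interval <- function(samples, level = 0.90,
                              method = c("equal_tailed", "highest_density")) {
  method <- match.arg(method)
  if (!length(samples)) abort("`samples` must be non-empty.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  if (length(samples) < 20L) {
    warn("Fewer than 20 samples: credible interval will be unstable.")
  } else if (length(samples) < 100L) {
    warn("Fewer than 100 samples: credible interval may be unstable.")
  }
  if (method == "equal_tailed") {
    qs <- quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE, type = 7)
    lo <- qs[1L]; hi <- qs[2L]
  } else {
    x <- sort(samples)
    n <- length(x)
    m <- min(n, max(1L, ceiling(level * n)))
    widths <- x[m:n] - x[seq_len(n - m + 1L)]
    i <- which.min(widths)
    lo <- x[i]; hi <- x[i + m - 1L]
  }
  tibble(lower = lo, upper = hi, level = level, method = method)
}

#' Per-feature rhythm statistics with credible intervals
#'
#' Draws posterior coefficient samples, converts them to rhythm-statistic
#' draws, applies the quarter-period sign-flip to the amplitude draws, and
#' summarizes each statistic by its posterior mean and credible interval.
#' The `peak_phase` row reports the amplitude-weighted circular mean phase
#' as the estimate (no interval: phase is circular).
#'
#' @param post A `rhythm_posterior`.
#' @param n_samples Number of posterior draws (default 200).
#' @param level Credible level (default 0.90).
#' @param method Interval method, `"equal_tailed"` or `"highest_density"`.
#' @param seed Integer seed for the draws.
#' @param grid_n Curve grid resolution (default 256).
#' @return A tibble with one row per feature and statistic: `feature_id`,
#'   `statistic`, `estimate`, `lower`, `upper`, `level`, `n_samples`,
#'   `method`. Amplitude rows are on the signed scale.
#' @export
rhythm_intervals <- function(post, n_samples = 200, level = 0.90,
                             method = c("equal_tailed", "highest_density"),
                             seed = NULL, grid_n = 256) {
  method <- match.arg(method)
  sd_ <- statistics_from_draws(post, n_samples = n_samples, seed = seed,
                               grid_n = grid_n)
  signed <- signed_amplitudes(sd_)
  mats <- list(
    mesor = sd_$mesor, peak = sd_$peak, trough = sd_$trough,
    ptt_amplitude = signed$ptt_amplitude,
    rms_amplitude = signed$rms_amplitude
  )
  feature_ids <- rownames(sd_$mesor)
  rows <- purrr::map_dfr(names(mats), function(s) {
    M <- mats[[s]]
    ci <- purrr::map_dfr(seq_len(nrow(M)), function(g) {
      suppressWarnings(credible_interval(M[g, ], level = level, method = method))
    })
    dplyr::bind_cols(
      tibble(feature_id = feature_ids, statistic = s,
             estimate = rowMeans(M)),
      ci[, c("lower", "upper")]
    )
  })
  phase_rows <- tibble(
    feature_id = feature_ids, statistic = "peak_phase",
    estimate = unname(signed$mean_peak_phase),
    lower = NA_real_, upper = NA_real_
  )
  dplyr::bind_rows(rows, phase_rows) |>
    dplyr::mutate(level = level, n_samples = n_samples, method = method) |>
    dplyr::arrange(match(.data$feature_id, feature_ids))
}
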