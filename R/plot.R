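#' Plot fitted curves with the underlying samples
#'
#' Shows measured values against time (modulo the period) with the averaged
#' fitted curve for selected features; with a `rhythm_posterior` both the
#' raw and posterior-mean curves are drawn.
#'
#' @param object A `rhythm_fit` or `rhythm_posterior`.
#' @param data The wide expression table the model was fitted to.
#' @param features Feature ids to plot (default: first 4).
#' @param grid_n Curve resolution (default 256).
#' @return A ggplot object, faceted by feature.
#' @export
plot_rhythm_fit <- function(object, data, features = NULL, grid_n = 256) {
  post <- NULL
  if (inherits(object, "rhythm_posterior")) {
    post <- object
    fit <- object$fit
  } else {
    stopifnot(inherits(object, "rhythm_fit"))
    fit <- object
  }
  if (is.null(features)) features <- utils::head(fit$feature_ids, 4L)
  mat <- as_feature_matrix(data, "data")[features, , drop = FALSE]
  pts <- tibble(
    feature_id = rep(features, times = ncol(mat)),
    time = rep(fit$time %% fit$period, each = length(features)),
    value = as.vector(mat)
  )
  grid <- curve_grid(fit$period, grid_n)
  curve_tbl <- function(f, label) {
    Y <- average_fits(f, grid, features = features)
    tibble(
      feature_id = rep(features, times = length(grid)),
      time = rep(grid, each = length(features)),
      value = as.vector(Y), fit_type = label
    )
  }
  curves <- curve_tbl(fit, "raw")
  if (!is.null(post)) {
    curves <- dplyr::bind_rows(curves, curve_tbl(posterior_fit(post),
                                                 "posterior_mean"))
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(colour = .data$fit_type), linewidth = 0.7
    ) +
    ggplot2::facet_wrap(~feature_id, scales = "free_y") +
    ggplot2::labs(x = "Time (h, mod period)", y = "Expression (log scale)",
                  colour = "Fit") +
    ggplot2::theme_bw()
}

#' @export
autoplot.rhythm_fit <- function(object, data, features = NULL, ...) {
  plot_rhythm_fit(object, data, features = features, ...)
}

#' @export
autoplot.rhythm_posterior <- function(object, data, features = NULL, ...) {
  plot_rhythm_fit(object, data, features = features, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of signed-amplitude credible intervals
#'
#' Shows each feature's posterior peak-to-trough amplitude with its credible
#' interval, ordered by amplitude; intervals crossing zero indicate
#' uncertain rhythmicity.
#'
#' @param intervals Output of [rhythm_intervals()].
#' @param statistic Which amplitude to plot (default `"ptt_amplitude"`).
#' @param top_n Show only the `top_n` features by estimate (default all).
#' @return A ggplot object.
#' @export
plot_amplitude_intervals <- function(intervals, statistic = "ptt_amplitude",
                                     top_n = NULL) {
  df <- dplyr::filter(intervals, .data$statistic == !!statistic) |>
    dplyr::arrange(dplyr::desc(.data$estimate))
  if (!is.null(top_n)) df <- utils::head(df, top_n)
  df$feature_id <- factor(df$feature_id, levels = rev(df$feature_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$feature_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("%s (signed, %g%% CI)", statistic,
                              100 * df$level[1L]),
                  y = NULL) +
    ggplot2::theme_bw()
}

#' Raw vs posterior amplitude scatter
#'
#' Visualizes the shrinkage: posterior-mean peak-to-trough amplitude against
#' the raw-fit amplitude, coloured by the mean standard error of the raw
#' fit. Noisier fits are pulled further below the identity line.
#'
#' @param statistics Combined statistics table from [run_rhythm_pipeline()]
#'   (or `bind_rows` of raw and posterior [rhythm_statistics()] tables).
#' @param post Optional `rhythm_posterior` supplying raw standard errors for
#'   the colour scale.
#' @return A ggplot object.
#' @export
plot_shrinkage <- function(statistics, post = NULL) {
  wide <- statistics |>
    dplyr::select("feature_id", "fit_type", "ptt_amplitude") |>
    tidyr::pivot_wider(names_from = "fit_type", values_from = "ptt_amplitude")
  if (!is.null(post)) {
    wide$mean_se <- rowMeans(post$raw_se)[wide$feature_id]
  }
  aes <- if (is.null(post)) {
    ggplot2::aes(x = .data$raw, y = .data$posterior_mean)
  } else {
    ggplot2::aes(x = .data$raw, y = .data$posterior_mean,
                 colour = log2(.data$mean_se))
  }
  ggplot2::ggplot(wide, aes) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Raw peak-to-trough amplitude",
                  y = "Posterior peak-to-trough amplitude",
                  colour = "log2 mean SE") +
    ggplot2::theme_bw()
}
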