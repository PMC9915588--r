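#' Simulate a rhythmic expression dataset with known ground truth
#'
#' Generates a feature-by-sample dataset emulating a circadian time-course
#' experiment: a fraction of features oscillate with known mesor,
#' peak-to-trough amplitude, peak phase and waveform; the rest are flat.
#' Gaussian mode returns log-scale values (waveform + normal noise); count
#' mode returns negative-binomial counts whose log2 mean follows the
#' waveform, scaled to a target library size.
#'
#' Waveforms are parameterized by a unit shape `u(t)` in `[0, 1]` peaking at
#' the feature's phase, so the generated curve is
#' `mesor + amplitude * (u(t) - mean(u))`: the peak-to-trough amplitude is
#' exactly `amplitude` and the time-average is exactly `mesor`. Shapes:
#' `"cosine"` (sinusoid), `"peaked"` (sharpened cosine, narrow peak), and
#' `"square"` (logistic-saturated cosine, flattened extremes).
#'
#' @param n_features Number of features (default 1000).
#' @param frac_rhythmic Fraction of rhythmic features (default 0.3).
#' @param n_timepoints Number of distinct timepoints (default 24).
#' @param spacing_h Hours between consecutive timepoints (default 2, i.e.
#'   every 2 h over 48 h with the default `n_timepoints`).
#' @param n_replicates Samples per timepoint (default 1).
#' @param period Period in hours (default 24).
#' @param amplitude_range Range of true peak-to-trough amplitudes (log2
#'   units) for rhythmic features (default `c(1, 4)`).
#' @param mesor_mean,mesor_sd Normal distribution of true mesors (default
#'   6 and 1.5 log2 units).
#' @param waveform `"cosine"`, `"peaked"`, or `"square"`; recycled across
#'   rhythmic features (default `"cosine"`).
#' @param noise_sd Gaussian noise SD on the log scale (default 0.2).
#' @param mode `"gaussian"` (log-scale values) or `"counts"`
#'   (negative-binomial counts).
#' @param dispersion Negative-binomial dispersion for count mode (default
#'   0.1).
#' @param lib_size Target library size per sample for count mode (default
#'   5e6).
#' @param batch_effect Optional additive offset applied to the second half
#'   of samples; when nonzero, metadata gains a `batch` column (default 0).
#' @param seed Integer seed (required, for reproducible fixtures).
#' @return A list of class `rhythm_simulation`: `data` (wide tibble),
#'   `metadata` (tibble `sample_id`, `time`, optional `batch`), `truth`
#'   (tibble of per-feature true statistics), and the evaluated
#'   configuration.
#' @export
simulate_rhythm_data <- function(n_features = 1000, frac_rhythmic = 0.3,
                                 n_timepoints = 24, spacing_h = 2,
                                 n_replicates = 1, period = 24,
                                 amplitude_range = c(1, 4),
                                 mesor_mean = 6, mesor_sd = 1.5,
                                 waveform = "cosine", noise_sd = 0.2,
                                 mode = c("gaussian", "counts"),
                                 dispersion = 0.1, lib_size = 5e6,
                                 batch_effect = 0, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("`seed` is required for reproducible simulations.")
  if (frac_rhythmic < 0 || frac_rhythmic > 1) abort("`frac_rhythmic` must be in [0, 1].")
  if (spacing_h <= 0) abort("`spacing_h` must be positive.")
  bad <- setdiff(waveform, names(waveform_shapes))
  if (length(bad)) {
    abort(sprintf("Unknown waveform(s): %s. Use one of: %s.",
                  paste(bad, collapse = ", "),
                  paste(names(waveform_shapes), collapse = ", ")))
  }
  set.seed(seed)
  time <- rep((seq_len(n_timepoints) - 1L) * spacing_h, each = n_replicates)
  S <- length(time)
  sample_ids <- sprintf("sample_%02d", seq_len(S))
  feature_ids <- sprintf("feature_%04d", seq_len(n_features))
  n_rhythmic <- round(frac_rhythmic * n_features)
  rhythmic <- seq_len(n_features) <= n_rhythmic
  amp <- ifelse(rhythmic,
                runif(n_features, amplitude_range[1L], amplitude_range[2L]), 0)
  phase <- ifelse(rhythmic, runif(n_features, 0, period), NA_real_)
  mesor <- rnorm(n_features, mesor_mean, mesor_sd)
  wf <- rep(NA_character_, n_features)
  wf[rhythmic] <- rep_len(waveform, n_rhythmic)
  mu <- matrix(rep(mesor, S), n_features, S)
  for (g in which(rhythmic)) {
    shape <- waveform_shapes[[wf[g]]]
    u <- shape$u((time - phase[g]) %% period, period)
    mu[g, ] <- mesor[g] + amp[g] * (u - shape$ubar)
  }
  if (batch_effect != 0) {
    second <- seq_len(S) > S / 2
    mu[, second] <- mu[, second] + batch_effect
  }
  if (mode == "gaussian") {
    vals <- mu + matrix(rnorm(n_features * S, 0, noise_sd), n_features, S)
  } else {
    rel <- 2^mu
    scaled <- sweep(rel, 2L, colSums(rel), "/") * lib_size
    vals <- matrix(
      stats::rnbinom(n_features * S, mu = scaled, size = 1 / dispersion),
      n_features, S
    )
  }
  dimnames(vals) <- list(feature_ids, sample_ids)
  truth <- purrr::map_dfr(seq_len(n_features), function(g) {
    truth_statistics(wf[g], amp[g], phase[g], mesor[g], period) |>
      dplyr::mutate(feature_id = feature_ids[g], rhythmic = rhythmic[g],
                    .before = 1L)
  })
  metadata <- tibble(sample_id = sample_ids, time = time)
  if (batch_effect != 0) {
    metadata$batch <- ifelse(seq_len(S) > S / 2, "b2", "b1")
  }
  structure(
    list(data = as_feature_tibble(vals), metadata = metadata, truth = truth,
         config = list(n_features = n_features, frac_rhythmic = frac_rhythmic,
                       n_timepoints = n_timepoints, spacing_h = spacing_h,
                       n_replicates = n_replicates, period = period,
                       amplitude_range = amplitude_range, waveform = waveform,
                       noise_sd = noise_sd, mode = mode,
                       dispersion = dispersion, batch_effect = batch_effect,
                       seed = seed)),
    class = "rhythm_simulation"
  )
}

#' @export
print.rhythm_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<rhythm_simulation> %d features (%.0f%% rhythmic), %d samples, %s noise, seed %d\n",
    cfg$n_features, 100 * cfg$frac_rhythmic, nrow(x$metadata), cfg$mode,
    cfg$seed
  ))
  invisible(x)
}

# Unit waveform shapes: u(dt, period) in [0, 1] with maximum 1 at dt = 0 and
# minimum 0; ubar is the period-average of u (closed form for the cosine,
# high-resolution quadrature otherwise, computed once at load).
make_shape <- function(u_fun, ubar = NULL) {
  if (is.null(ubar)) {
    dt <- 24 * (seq_len(1e5) - 0.5) / 1e5
    ubar <- mean(u_fun(dt, 24))
  }
  list(u = u_fun, ubar = ubar)
}

waveform_shapes <- list(
  cosine = make_shape(function(dt, period) (1 + cos(2 * pi * dt / period)) / 2,
                      ubar = 0.5),
  peaked = make_shape(function(dt, period) ((1 + cos(2 * pi * dt / period)) / 2)^4),
  square = make_shape(function(dt, period) {
    k <- 3
    raw <- stats::plogis(k * cos(2 * pi * dt / period))
    (raw - stats::plogis(-k)) / (stats::plogis(k) - stats::plogis(-k))
  })
)

#' True rhythm statistics of a generating waveform
#'
#' Closed form for the cosine shape; 1e5-point quadrature for the others.
#' Arrhythmic features (NA waveform or zero amplitude) get zero amplitudes
#' and NA phases.
#'
#' @param waveform Shape name or `NA` for an arrhythmic feature.
#' @param amplitude True peak-to-trough amplitude.
#' @param phase True peak phase in hours.
#' @param mesor True mesor.
#' @param period Period in hours.
#' @return One-row tibble of the seven true statistics plus the waveform.
#' @export
truth_statistics <- function(waveform, amplitude, phase, mesor, period = 24) {
  if (is.na(waveform) || amplitude == 0) {
    return(tibble(
      mesor = mesor, peak = mesor, peak_phase = NA_real_, trough = mesor,
      trough_phase = NA_real_, ptt_amplitude = 0, rms_amplitude = 0,
      waveform = NA_character_
    ))
  }
  shape <- waveform_shapes[[waveform]]
  rms_unit <- if (waveform == "cosine") {
    0.5 / sqrt(2)
  } else {
    dt <- period * (seq_len(1e5) - 0.5) / 1e5
    sqrt(mean((shape$u(dt, period) - shape$ubar)^2))
  }
  dt <- period * (seq_len(1e5) - 1) / 1e5
  uu <- shape$u(dt, period)
  trough_dt <- dt[which.min(uu)]
  tibble(
    mesor = mesor,
    peak = mesor + amplitude * (1 - shape$ubar),
    peak_phase = phase %% period,
    trough = mesor - amplitude * shape$ubar,
    trough_phase = (phase + trough_dt) %% period,
    ptt_amplitude = amplitude,
    rms_amplitude = amplitude * rms_unit,
    waveform = waveform
  )
}
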