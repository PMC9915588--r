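test_that("noiseless model-spanned signals are interpolated exactly", {
  md <- make_metadata(24)
  b <- time_basis("periodic_spline", 24, 3)
  X <- build_design(md, b)
  beta <- rbind(c(5, 1, -0.5, 0.25), c(-2, 0, 2, 1))
  Y <- beta %*% t(X)
  dimnames(Y) <- list(c("g1", "g2"), md$sample_id)
  fit <- suppressWarnings(fit_rhythm_models(Y, md, n_shifts = 1))
  expect_equal(unname(fit$coef[[1]]), unname(beta), tolerance = 1e-8)
})

test_that("coefficients match an independent normal-equations solve", {
  md <- make_metadata(15, by = 1.7)
  set.seed(21)
  for (rep in 1:5) {
    Y <- matrix(rnorm(4 * 15), 4, 15,
                dimnames = list(paste0("g", 1:4), md$sample_id))
    fit <- fit_rhythm_models(Y, md, n_knots = 3, n_shifts = 2)
    for (k in 1:2) {
      X <- fit$designs[[k]]
      oracle <- t(solve(t(X) %*% X) %*% t(X) %*% t(Y))
      expect_lt(max(abs(fit$coef[[k]] - oracle)), 1e-8)
      # SE oracle from s^2 * diag((X'X)^-1)
      res <- Y - fit$coef[[k]] %*% t(X)
      s2 <- rowSums(res^2) / (ncol(Y) - ncol(X))
      se_oracle <- sqrt(outer(s2, diag(solve(t(X) %*% X))))
      expect_lt(max(abs(fit$se[[k]] - se_oracle)), 1e-8)
    }
  }
})

test_that("standard errors estimate the true sampling variance of coefficients", {
  # 2000 replicate features with the same design and known noise give both
  # the empirical sampling variance and the mean squared SE
  md <- make_metadata(20)
  sigma <- 0.7
  set.seed(31)
  Y <- matrix(rnorm(2000 * 20, mean = 3, sd = sigma), 2000, 20,
              dimnames = list(paste0("g", 1:2000), md$sample_id))
  fit <- fit_rhythm_models(Y, md, n_shifts = 1)
  emp_var <- apply(fit$coef[[1]], 2, var)
  mean_se2 <- colMeans(fit$se[[1]]^2)
  expect_equal(unname(mean_se2 / emp_var), rep(1, 4), tolerance = 0.05)
})

test_that("OLS residuals are orthogonal to the design columns", {
  md <- make_metadata(18)
  set.seed(41)
  Y <- matrix(rnorm(6 * 18), 6, 18,
              dimnames = list(paste0("g", 1:6), md$sample_id))
  fit <- fit_rhythm_models(Y, md)
  for (k in seq_len(fit$n_shifts)) {
    R <- Y - fit$coef[[k]] %*% t(fit$designs[[k]])
    expect_lt(max(abs(R %*% fit$designs[[k]])), 1e-6)
  }
})

test_that("cosinor fit recovers sinusoid amplitude and phase", {
  md <- make_metadata(24)
  Y <- make_sinusoid_matrix(md$time, mesor = c(4, 7), amp_half = c(2, 0.5),
                            phase = c(3, 17))
  fit <- suppressWarnings(fit_rhythm_models(Y, md, method = "cosinor"))
  st <- rhythm_statistics(fit)
  expect_equal(st$ptt_amplitude, c(4, 1), tolerance = 1e-8)
  expect_equal(st$peak_phase, c(3, 17), tolerance = 1e-6)

  # noisy Monte-Carlo: amplitude estimates unbiased
  set.seed(8)
  Yn <- make_sinusoid_matrix(rep(md$time, 1), mesor = rep(5, 400),
                             amp_half = rep(1, 400), phase = rep(6, 400),
                             noise_sd = 0.3)
  stn <- rhythm_statistics(fit_rhythm_models(Yn, md, method = "cosinor"))
  expect_equal(mean(stn$ptt_amplitude), 2, tolerance = 0.02)
  expect_equal(mean(stn$peak_phase), 6, tolerance = 0.05)
})

test_that("evaluate_fit matches the design-coefficient product and is periodic", {
  md <- make_metadata(16)
  set.seed(51)
  Y <- matrix(rnorm(3 * 16), 3, 16,
              dimnames = list(paste0("g", 1:3), md$sample_id))
  fit <- fit_rhythm_models(Y, md)
  tnew <- c(0.5, 7.25, 19.8)
  for (k in 1:3) {
    pred <- evaluate_fit(fit, tnew, "g2", shift = k)
    Xn <- cbind(1, eval_basis(fit$bases[[k]], tnew))
    expect_equal(pred, drop(Xn %*% fit$coef[[k]]["g2", ]), tolerance = 1e-10)
    expect_equal(pred, evaluate_fit(fit, tnew + 24, "g2", shift = k),
                 tolerance = 1e-10)
  }
})

test_that("an intercept-only signal evaluates to a constant", {
  md <- make_metadata(16)
  Y <- matrix(5, 2, 16, dimnames = list(c("g1", "g2"), md$sample_id))
  fit <- suppressWarnings(fit_rhythm_models(Y, md))
  expect_equal(unname(evaluate_fit(fit, c(0, 3, 11), "g1")), rep(5, 3),
               tolerance = 1e-8)
})

test_that("average_fits is the pointwise mean of the shifted model curves", {
  md <- make_metadata(20)
  set.seed(61)
  Y <- matrix(rnorm(4 * 20, 5), 4, 20,
              dimnames = list(paste0("g", 1:4), md$sample_id))
  fit <- fit_rhythm_models(Y, md, n_shifts = 3)
  tg <- seq(0, 23, by = 1.5)
  avg <- average_fits(fit, tg, features = "g3")
  manual <- rowMeans(sapply(1:3, function(k) evaluate_fit(fit, tg, "g3", k)))
  expect_equal(unname(avg[1, ]), manual, tolerance = 1e-10)

  fit1 <- fit_rhythm_models(Y, md, n_shifts = 1)
  expect_equal(unname(average_fits(fit1, tg, "g3")[1, ]),
               evaluate_fit(fit1, tg, "g3"), tolerance = 1e-12)
})

test_that("averaging over shifts beats the worst single shifted model", {
  # fixed non-sinusoidal waveform not in the spline span
  md <- make_metadata(24)
  shape <- function(t) {
    c <- cos(2 * pi * (t - 8) / 24)
    sign(c) * abs(c)^3
  }
  Y <- matrix(shape(md$time), 1, 24,
              dimnames = list("g1", md$sample_id))
  fit <- suppressWarnings(fit_rhythm_models(Y, md, n_shifts = 3))
  tg <- curve_grid <- 24 * (0:255) / 256
  truth <- shape(tg)
  worst <- max(sapply(1:3, function(k) {
    max(abs(evaluate_fit(fit, tg, "g1", k) - truth))
  }))
  avg_dev <- max(abs(average_fits(fit, tg, "g1")[1, ] - truth))
  expect_lt(avg_dev, worst)
})

test_that("variance moderation pools toward the prior without leaving the s^2 range", {
  md <- make_metadata(16)
  set.seed(71)
  Y <- matrix(rnorm(100 * 16, sd = rep(runif(100, 0.3, 2), 16)), 100, 16,
              dimnames = list(paste0("g", 1:100), md$sample_id))
  fit <- fit_rhythm_models(Y, md, n_shifts = 1)
  mod <- moderate_variances(fit)
  s2 <- fit$sigma2[, 1]
  s2m <- mod$sigma2[, 1]
  prior <- rhythmeb:::fit_inverse_chisq_prior(s2, fit$df_resid)
  # convex combination: moderated values lie between raw s^2 and the prior
  expect_true(all(s2m >= pmin(s2, prior$s0_sq) - 1e-12))
  expect_true(all(s2m <= pmax(s2, prior$s0_sq) + 1e-12))
  # SEs rescaled consistently
  expect_equal(mod$se[[1]] / fit$se[[1]],
               matrix(sqrt(s2m / s2), 100, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("identical residual variances are left unchanged by moderation", {
  md <- make_metadata(12)
  b <- time_basis("periodic_spline", 24, 3)
  X <- build_design(md, b)
  set.seed(81)
  beta <- matrix(rnorm(30 * 4), 30, 4)
  E <- matrix(rnorm(12), 1, 12) # same residual vector for every feature
  Y <- beta %*% t(X) + E[rep(1, 30), ]
  dimnames(Y) <- list(paste0("g", 1:30), md$sample_id)
  fit <- fit_rhythm_models(Y, md, n_shifts = 1)
  mod <- moderate_variances(fit)
  expect_equal(mod$sigma2, fit$sigma2, tolerance = 1e-8)
})

test_that("moderation refuses tiny feature sets", {
  md <- make_metadata(12)
  Y <- matrix(rnorm(2 * 12), 2, 12,
              dimnames = list(c("g1", "g2"), md$sample_id))
  fit <- fit_rhythm_models(Y, md, n_shifts = 1)
  expect_error(moderate_variances(fit), "at least 3")
})

test_that("tidy and glance summarize a fit", {
  md <- make_metadata(14)
  set.seed(91)
  Y <- matrix(rnorm(3 * 14), 3, 14,
              dimnames = list(paste0("g", 1:3), md$sample_id))
  fit <- fit_rhythm_models(Y, md)
  td <- tidy(fit)
  expect_equal(nrow(td), 3 * 3 * 4) # features x shifts x coefficients
  expect_true(all(td$std.error >= 0))
  gl <- glance(fit)
  expect_equal(gl$n_features, 3L)
  expect_equal(gl$df_resid, 10)
})
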