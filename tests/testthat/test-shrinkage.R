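test_that("strong-signal selection ranks by max |z| and ignores row order", {
  set.seed(101)
  N <- 50
  B <- matrix(rnorm(N * 4, sd = 0.1), N, 4)
  B[7, 1] <- 50
  S <- matrix(1, N, 4)
  fit <- fake_fit(B, S, n_shifts = 2)
  sel <- select_strong_signals(fit, top_frac = 0.1)
  expect_length(sel, 5L)
  expect_true("f7" %in% sel[1])

  perm <- sample(N)
  fitp <- fake_fit(B[perm, ], S[perm, ], n_shifts = 2)
  fitp$feature_ids <- fit$feature_ids[perm]
  for (k in 1:2) {
    rownames(fitp$coef[[k]]) <- rownames(fitp$se[[k]]) <- fitp$feature_ids
  }
  expect_setequal(select_strong_signals(fitp, top_frac = 0.1), sel)

  expect_error(select_strong_signals(fit, top_frac = 0), "top_frac")
  expect_error(select_strong_signals(fit, top_frac = 1.5), "top_frac")
})

test_that("data-driven covariances match an SVD of the centered effects", {
  set.seed(111)
  X <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(3, 2, 1, 0.2, 0.1, 0.05))
  Us <- data_driven_covariances(X, n_pc = 3)
  expect_length(Us, 4L) # 3 rank-1 + 1 reconstruction
  sv <- svd(scale(X, center = TRUE, scale = FALSE))
  for (j in 1:3) {
    U <- Us[[paste0("pca_", j)]]
    v <- sv$v[, j]
    oracle <- tcrossprod(v) / max(diag(tcrossprod(v)))
    expect_lt(max(abs(U - oracle)), 1e-8)
    expect_lt(max(abs(U - t(U))), 1e-12)
    expect_gt(min(eigen(U, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
  # rank-1 data give a covariance proportional to v v'
  v <- c(1, -2, 0.5)
  X1 <- outer(rnorm(30), v)
  U1 <- data_driven_covariances(X1, n_pc = 1)[["pca_1"]]
  expect_lt(max(abs(U1 - tcrossprod(v) / max(v^2))), 1e-6)

  expect_error(data_driven_covariances(matrix(0, 10, 3), 1), "all zero")
})

test_that("the scale grid is geometric, increasing, and spans the effects", {
  set.seed(121)
  B <- matrix(rnorm(30 * 4), 30, 4)
  S <- matrix(runif(30 * 4, 0.1, 0.5), 30, 4)
  fit <- fake_fit(B, S, n_shifts = 2)
  g <- scale_grid(fit)
  expect_true(all(diff(g) > 0))
  expect_gte(max(g), max(B^2))
  expect_equal(g[-1] / g[-length(g)], rep(2, length(g) - 1), tolerance = 1e-10)
  # halving the multiplier roughly doubles the grid length
  g2 <- scale_grid(fit, grid_mult = sqrt(sqrt(2)))
  expect_gt(length(g2), 1.8 * length(g))
  expect_lt(length(g2), 2.4 * length(g))
})

test_that("EM leaves a single-component prior at weight one", {
  set.seed(131)
  B <- matrix(rnorm(20), 20, 1)
  S <- matrix(1, 20, 1)
  fit <- fake_fit(B, S)
  prior <- structure(
    list(U = list(only = matrix(1, 1, 1)),
         components = tibble::tibble(U_name = "only", omega = 1),
         pi = NULL, grid = 1, loglik_trace = NULL),
    class = "shrinkage_prior"
  )
  fitted <- fit_mixture_weights(fit, prior)
  expect_equal(unname(fitted$pi), 1)
})

test_that("EM recovers a dominant null component from null data", {
  set.seed(141)
  N <- 2000
  B <- matrix(rnorm(N, 0, 1), N, 1) # pure error, SE = 1
  S <- matrix(1, N, 1)
  fit <- fake_fit(B, S)
  prior <- make_prior(list(signal = matrix(1, 1, 1)), grid = 25)
  fitted <- fit_mixture_weights(fit, prior)
  null_w <- fitted$pi[fitted$components$U_name == "null"]
  expect_gte(unname(null_w), 0.95)
})

test_that("marginal log-likelihood is monotone nondecreasing over EM iterations", {
  set.seed(151)
  B <- matrix(rnorm(200 * 2, 0, 1.5), 200, 2)
  S <- matrix(1, 200, 2)
  fit <- fake_fit(B, S, n_shifts = 1)
  prior <- make_prior(list(identity = diag(2),
                           corr = matrix(c(1, .9, .9, 1), 2)),
                      grid = c(0.5, 2, 8))
  fitted <- fit_mixture_weights(fit, prior)
  expect_gt(length(fitted$loglik_trace), 1L)
  expect_true(all(diff(fitted$loglik_trace) >= -1e-9))
})

test_that("scalar posterior matches the conjugate normal-normal closed form", {
  tau2 <- 4; s <- 1.5
  B <- matrix(c(-2, 0.3, 5), 3, 1)
  S <- matrix(s, 3, 1)
  fit <- fake_fit(B, S)
  prior <- structure(
    list(U = list(signal = matrix(1, 1, 1)),
         components = tibble::tibble(U_name = "signal", omega = tau2),
         pi = 1, grid = tau2, loglik_trace = 0, error_corr = NULL),
    class = "shrinkage_prior"
  )
  post <- compute_posteriors(fit, prior)
  expect_equal(unname(post$post_mean[, 1]), B[, 1] * tau2 / (tau2 + s^2),
               tolerance = 1e-10)
  expect_equal(unname(post$post_sd[, 1]),
               rep(sqrt(tau2 * s^2 / (tau2 + s^2)), 3), tolerance = 1e-10)
})

test_that("zero standard errors return the raw estimates", {
  B <- matrix(c(1.7, -0.4), 2, 1)
  S <- matrix(0, 2, 1)
  fit <- fake_fit(B, S)
  prior <- make_prior(list(signal = matrix(1, 1, 1)), grid = c(1, 10))
  fitted <- fit_mixture_weights(fit, prior)
  post <- compute_posteriors(fit, fitted)
  expect_equal(unname(post$post_mean[, 1]), B[, 1], tolerance = 1e-6)
})

test_that("a pure null prior shrinks everything to zero", {
  B <- matrix(rnorm(5), 5, 1)
  S <- matrix(1, 5, 1)
  fit <- fake_fit(B, S)
  p <- 1
  prior <- structure(
    list(U = list(null = matrix(0, 1, 1)),
         components = tibble::tibble(U_name = "null", omega = 1),
         pi = 1, grid = 1, loglik_trace = 0, error_corr = NULL),
    class = "shrinkage_prior"
  )
  post <- compute_posteriors(fit, prior)
  expect_equal(unname(post$post_mean[, 1]), rep(0, 5))
  expect_equal(unname(post$post_sd[, 1]), rep(0, 5))
  draws <- sample_posterior(post, 10, seed = 1)
  expect_true(all(draws == 0))
})

test_that("posterior draws are reproducible and average to the posterior mean", {
  set.seed(161)
  B <- matrix(rnorm(4 * 2, 0, 2), 4, 2)
  S <- matrix(0.8, 4, 2)
  fit <- fake_fit(B, S, n_shifts = 1)
  prior <- make_prior(list(identity = diag(2)), grid = c(1, 4, 16))
  post <- compute_posteriors(fit, fit_mixture_weights(fit, prior))
  d1 <- sample_posterior(post, 50, seed = 99)
  d2 <- sample_posterior(post, 50, seed = 99)
  expect_identical(d1, d2)

  dbig <- sample_posterior(post, 20000, seed = 100)
  mc_mean <- apply(dbig, c(1, 3), mean)
  mc_se <- apply(dbig, c(1, 3), sd) / sqrt(20000)
  expect_true(all(abs(mc_mean - post$post_mean) <= 3 * mc_se + 1e-8))
})

test_that("shrinkage pulls noisy null features toward zero", {
  set.seed(171)
  sim <- simulate_rhythm_data(n_features = 150, frac_rhythmic = 0.3,
                              noise_sd = 0.4, n_timepoints = 12,
                              spacing_h = 2, seed = 172)
  fit <- fit_rhythm_models(sim$data, sim$metadata)
  post <- moderate_fits(fit)
  sr <- rhythm_statistics(fit)
  sp <- rhythm_statistics(post)
  nullf <- !sim$truth$rhythmic
  expect_lt(mean(sp$ptt_amplitude[nullf]), mean(sr$ptt_amplitude[nullf]))
})
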