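test_that("odd/even split follows 1-based session order", {
  s4 <- random_session(4)
  sp <- split_train_valid(s4)
  expect_identical(sp$train_idx, c(1L, 3L))
  expect_identical(sp$valid_idx, c(2L, 4L))
  expect_equal(sp$train$fluorescence, s4$fluorescence[c(1, 3), , ])
  s2 <- random_session(2)
  sp2 <- split_train_valid(s2)
  expect_equal(n_trials(sp2$train), 1L)
  expect_equal(n_trials(sp2$valid), 1L)
  s5 <- random_session(5)
  sp5 <- split_train_valid(s5)
  expect_equal(n_trials(sp5$train), 3L)
  expect_equal(n_trials(sp5$valid), 2L)
  expect_error(split_train_valid(subset_trials(s5, 1)))
})

test_that("gaussian log-likelihood matches closed forms and a
           density-product oracle", {
  expect_equal(gaussian_log_likelihood(0.3, 0.3, 1), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  s <- 0.7
  expect_equal(gaussian_log_likelihood(s, 0, s^2),
               -0.5 * log(2 * pi * s^2) - 0.5, tolerance = 1e-12)
  set.seed(11)
  y <- matrix(rnorm(25), 5); m <- matrix(rnorm(25), 5)
  v <- matrix(runif(25, 0.2, 2), 5)
  oracle <- sum(dnorm(y, m, sqrt(v), log = TRUE))
  expect_equal(gaussian_log_likelihood(y, m, v), oracle,
               tolerance = 1e-10)
  expect_error(gaussian_log_likelihood(y, m, v * 0))
  expect_error(gaussian_log_likelihood(y, m[1:4, 1:4], v))
})

test_that("diagonal-Gaussian KL matches closed forms and quadrature", {
  expect_equal(kl_diag_gaussians(c(1, 2), c(0.5, 3), c(1, 2), c(0.5, 3)),
               0, tolerance = 1e-12)
  expect_equal(kl_diag_gaussians(0, 1, 0, exp(1)),
               0.5 * (1 / exp(1) + 0 - 1 + 1), tolerance = 1e-12)
  set.seed(12)
  mq <- rnorm(3); vq <- runif(3, 0.3, 2)
  mp <- rnorm(3); vp <- runif(3, 0.3, 2)
  quad <- sum(vapply(1:3, function(i) {
    integrate(function(x) {
      q <- dnorm(x, mq[i], sqrt(vq[i]))
      ifelse(q > 0, q * (dnorm(x, mq[i], sqrt(vq[i]), log = TRUE) -
                           dnorm(x, mp[i], sqrt(vp[i]), log = TRUE)), 0)
    }, -30, 30, rel.tol = 1e-10)$value
  }, 0))
  expect_equal(kl_diag_gaussians(mq, vq, mp, vp), quad,
               tolerance = 1e-6)
  expect_error(kl_diag_gaussians(0, -1, 0, 1))
})

test_that("inference is strictly causal", {
  mod <- tiny_model()
  base <- random_session(3, 10, 5, seed = 21)
  for (rep in 1:10) {
    t_cut <- sample(2:9, 1)
    pert <- base
    set.seed(100 + rep)
    pert$fluorescence[, (t_cut + 1):10, ] <-
      pert$fluorescence[, (t_cut + 1):10, ] + rnorm(3 * (10 - t_cut) * 5)
    p0 <- forward_causal(mod, base, "mean")
    p1 <- forward_causal(mod, pert, "mean")
    expect_identical(p0$inferred_inputs[, 1:t_cut, ],
                     p1$inferred_inputs[, 1:t_cut, ])
    expect_identical(p0$factors[, 1:t_cut, ], p1$factors[, 1:t_cut, ])
    expect_identical(p0$denoised_means[, 1:t_cut, ],
                     p1$denoised_means[, 1:t_cut, ])
    expect_identical(p0$ic_mean, p1$ic_mean)
  }
})

test_that("ELBO components decompose and sampling is reproducible", {
  mod <- tiny_model()
  ses <- random_session(4, 8, 5, seed = 22)
  p <- forward_causal(mod, ses, "mean")
  e <- p$elbo_components
  expect_equal(e$elbo, e$reconstruction - e$kl_g0 - e$kl_u,
               tolerance = 1e-8)
  expect_true(is.finite(e$elbo))
  s1 <- forward_causal(mod, ses, "sample", seed = 5)
  s2 <- forward_causal(mod, ses, "sample", seed = 5)
  expect_identical(s1$denoised_means, s2$denoised_means)
  s3 <- forward_causal(mod, ses, "sample", seed = 6)
  expect_false(identical(s1$denoised_means, s3$denoised_means))
})

test_that("training improves the objective deterministically", {
  sys <- make_system("line", 3, 8, seed = 31)
  ses <- simulate_session(sys, 16, bins_per_trial = 14, seed = 31)
  cfg <- lfads_config("small", n_generator = 12, n_factors = 4,
                      n_encoder = 8, n_controller = 8, max_epochs = 60,
                      kl_warmup = 10, seed = 31)
  mod <- lfads(ses, cfg)
  tc <- mod$training_curve
  expect_lt(tc$loss[nrow(tc)], tc$loss[1])
  mod2 <- lfads(ses, cfg)
  expect_identical(mod$params, mod2$params)
  # heavy recurrent L2 shrinks the recurrent kernels
  cfg_l2 <- cfg; cfg_l2$l2_penalty <- 1e6
  mod_l2 <- lfads(ses, cfg_l2)
  nrm <- function(m) sum(m$params$gen_Ur^2) + sum(m$params$gen_Uz^2) +
    sum(m$params$gen_Un^2)
  expect_lt(nrm(mod_l2), nrm(mod))
})

test_that("degenerate data and bad configs are rejected", {
  ses <- random_session(4, 8, 3, seed = 41)
  ses$fluorescence[, , 2] <- 1   # zero-variance neuron
  expect_error(lfads(ses, lfads_config("small")), "variance")
  expect_error(lfads_config("small", dropout_keep_rate = 0))
  expect_error(lfads_config("small", n_factors = 0))
  expect_error(lfads_config("small", l2_penalty = -1))
})

test_that("posterior averaging reduces to the mean pass and converges", {
  mod <- tiny_model()
  ses <- random_session(3, 8, 5, seed = 51)
  pm <- forward_causal(mod, ses, "mean")
  p1 <- posterior_average(mod, ses, n_samples = 1, mode = "mean")
  expect_equal(p1$denoised_means, pm$denoised_means, tolerance = 1e-12)
  ref <- posterior_average(mod, ses, n_samples = 128, seed = 0)
  a4 <- posterior_average(mod, ses, n_samples = 4, seed = 0)
  a64 <- posterior_average(mod, ses, n_samples = 64, seed = 0)
  err <- function(a) max(abs(a$denoised_means - ref$denoised_means))
  expect_lt(err(a64), err(a4))
  b1 <- posterior_average(mod, ses, n_samples = 8, seed = 3)
  b2 <- posterior_average(mod, ses, n_samples = 8, seed = 3)
  expect_identical(b1$denoised_means, b2$denoised_means)
})
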