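test_that("make_system builds the advertised eigenstructure", {
  line <- make_system("line", 4, 30, seed = 0)
  expect_true(validate_system(line))
  ev <- eigen(line$update_matrix, only.values = TRUE)$values
  expect_equal(sum(abs(Mod(ev) - 1) < 1e-10), 1L)
  expect_equal(sqrt(sum(line$integration_mode^2)), 1, tolerance = 1e-10)
  expect_gt(sum(line$input_rewarded$direction * line$integration_mode), 0)
  # unrewarded pulse orthogonal to the integration mode
  expect_lt(abs(sum(line$input_unrewarded$direction *
                      line$integration_mode)), 1e-10)

  pt <- make_system("point", 4, 30, seed = 0)
  expect_true(validate_system(pt))
  expect_lt(max(Mod(eigen(pt$update_matrix, only.values = TRUE)$values)), 1)

  expect_error(make_system("ring"))
  expect_error(make_system("line", n_latent = 1))
  expect_error(make_system("line", n_neurons = 0))

  a <- make_system("line", 5, 12, seed = 42)
  b <- make_system("line", 5, 12, seed = 42)
  expect_identical(a, b)
})

test_that("calcium kernel is causal with unit DC gain", {
  bin <- 0.2; tau <- 0.4
  phi <- exp(-bin / tau)
  # impulse on flat background decays geometrically with ratio phi
  y <- calcium_convolve(c(1, rep(0, 10)), tau, bin)
  expect_equal(y[-1] / head(y, -1), rep(phi, 10), tolerance = 1e-12)
  # constant input reproduced exactly
  expect_equal(calcium_convolve(rep(3.5, 20), tau, bin), rep(3.5, 20))
  # arbitrary input matches the O(T^2) convolution-sum oracle
  set.seed(3)
  x <- rnorm(50)
  expect_equal(calcium_convolve(x, 0.7, 0.1),
               convolve_oracle(x, 0.7, 0.1), tolerance = 1e-10)
  expect_error(calcium_convolve(x, -1, 0.1))
  expect_error(calcium_convolve(x, 0.4, 0))
})

test_that("zero dynamics yield constant fluorescence at the offset", {
  sys <- make_system("line", 4, 8, seed = 1, noise_sd = 0)
  sys$input_rewarded$amplitude <- 0
  sys$input_unrewarded$amplitude <- 0
  sys$input_cue$amplitude <- 0
  ses <- simulate_session(sys, 5, seed = 1)
  for (j in seq_len(8))
    expect_equal(as.numeric(ses$fluorescence[, , j]),
                 rep(sys$rate_offset[j], 5 * 40), tolerance = 1e-10)
})

test_that("eigenvalue-1 mode sums rewarded pulses exactly", {
  # closed form: with the pulse aligned to the integration mode, the
  # final projection equals (number of pulse bins) * amplitude per trial
  sys <- make_system("line", 4, 10, seed = 2, noise_sd = 0)
  a <- 0.3
  sys$input_rewarded <- list(direction = sys$integration_mode,
                             offsets = 4L, amplitude = a)
  sys$input_cue$amplitude <- 0
  n <- 7
  ses <- simulate_session(sys, n, p_reward = 1, seed = 2)
  lat <- attr(ses, "latents")
  final <- lat[n, 40, ]
  expect_equal(sum(final * sys$integration_mode), n * a,
               tolerance = 1e-8)
  # independent oracle: direct matrix iteration
  x <- numeric(4)
  for (k in seq_len(n)) for (t in 1:40) {
    x <- as.numeric(sys$update_matrix %*% x)
    if (t == 10) x <- x + a * sys$integration_mode   # cue_bin 6 + offset 4
  }
  expect_equal(final, x, tolerance = 1e-8)
})

test_that("point-attractor transients contract at the spectral radius", {
  sys <- make_system("point", 4, 6, seed = 3, noise_sd = 0)
  # make the spectral radius exactly 0.5
  Q <- eigen(sys$update_matrix, symmetric = TRUE)$vectors
  sys$update_matrix <- Q %*% diag(c(0.5, 0.4, 0.3, 0.2)) %*% t(Q)
  sys$integration_mode <- Q[, 1]
  sys$input_rewarded <- list(direction = Q[, 1], offsets = 0L,
                             amplitude = 1)
  sys$input_unrewarded <- sys$input_rewarded
  sys$input_cue$amplitude <- 0
  ses <- simulate_session(sys, 1, p_reward = 1, bins_per_trial = 30,
                          seed = 3, cue_bin = 5)
  lat <- attr(ses, "latents")[1, , ]
  norm5 <- sqrt(sum(lat[5, ]^2))     # right after the pulse
  for (t in 6:30)
    expect_lte(sqrt(sum(lat[t, ]^2)), 0.5^(t - 5) * norm5 + 1e-12)
})

test_that("sessions carry over state and are deterministic in the seed", {
  sys <- make_system("line", 4, 6, seed = 4)
  s1 <- simulate_session(sys, 12, seed = 9)
  s2 <- simulate_session(sys, 12, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_session(sys, 12, seed = 10)
  expect_false(identical(s1$fluorescence, s3$fluorescence))
  # with reset the pre-cue baseline does not ramp (noiseless check)
  sys0 <- make_system("line", 4, 6, seed = 4, noise_sd = 0)
  sr <- simulate_session(sys0, 10, seed = 9, reset_between_trials = TRUE)
  lat <- attr(sr, "latents")
  first_bins <- lat[, 1, ]
  expect_lt(max(abs(sweep(first_bins, 2, first_bins[1, ]))), 1e-10)
  expect_error(simulate_session(sys, 0))
  expect_error(simulate_session(sys, 5, p_reward = 1.2))
})

test_that("mean integrated evidence is monotone in reward probability", {
  sys <- make_system("line", 4, 5, seed = 5, noise_sd = 0)
  m <- sys$integration_mode
  finals <- sapply(c(0.5, 0.8, 1.0), function(p) {
    mean(vapply(seq_len(200), function(s) {
      ses <- simulate_session(sys, 20, p_reward = p, bins_per_trial = 15,
                              seed = s)
      lat <- attr(ses, "latents")
      sum(lat[20, 15, ] * m)
    }, 0))
  })
  expect_true(all(diff(finals) >= 0))
})
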