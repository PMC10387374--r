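test_that("Wilcoxon signed-rank matches the sign-enumeration oracle", {
  # n = 6, all differences positive: exact two-sided p = 2/2^6
  w <- wilcoxon_signed_rank(6:1 + 10, 6:1)
  expect_equal(w$p.value, 2 / 2^6)
  expect_identical(w$method, "exact")
  # all-zero differences rejected
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4, 4.5),
                                    c(1, 2, 3, 4, 5)), "at least 5")
  # 100 random n <= 12 instances vs the full enumeration oracle,
  # including ties and zero differences
  set.seed(91)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    d <- sample(c(-3:-1, 1:4), n, replace = TRUE)
    if (all(d > 0) || all(d < 0) || all(d == 0)) d[1] <- -d[1]
    alt <- sample(c("two.sided", "greater", "less"), 1)
    got <- wilcoxon_signed_rank(d + 100, rep(100, n), alternative = alt)
    expect_equal(got$p.value, wilcoxon_enum_oracle(d, alt),
                 tolerance = 1e-12)
  }
  # large-n normal approximation agrees with the base implementation
  set.seed(92)
  a <- rnorm(40); b <- rnorm(40)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                      exact = FALSE, correct = TRUE))
  expect_identical(ours$method, "normal")
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg matches the definitional oracle", {
  r <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$reject))
  expect_equal(benjamini_hochberg(0.037)$adjusted, 0.037)
  set.seed(93)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))^2
    expect_equal(benjamini_hochberg(p)$adjusted, bh_oracle(p))
    expect_equal(benjamini_hochberg(p)$adjusted, p.adjust(p, "BH"))
  }
  expect_error(benjamini_hochberg(c(0.1, 1.7)))
})

test_that("task modulation flags real steps and spares null neurons", {
  bin <- 0.5; cue <- 5L; nb <- 14L; n_tr <- 20L
  set.seed(94)
  # neuron 1: null; neuron 2: +5 step in the second post-cue window
  rates <- array(rnorm(n_tr * nb * 2, 10, 1), c(n_tr, nb, 2))
  w2 <- (cue + 2):(cue + 3)          # 1-2 s from cue at 0.5 s bins
  rates[, w2, 2] <- rates[, w2, 2] + 5
  res <- task_modulated(rates, cue, bin)
  expect_false(res$modulated[1])
  expect_true(res$modulated[2])
  expect_lt(res$p_adjusted[2, 2], 0.01)
  # constant-rate neuron: never modulated
  resc <- task_modulated(array(3, c(6, nb, 1)), cue, bin)
  expect_false(resc$modulated[1])
  expect_error(task_modulated(rates[1:3, , , drop = FALSE], cue, bin),
               "at least 5")
})

test_that("task-modulation false positives stay within the FDR budget", {
  set.seed(95)
  bin <- 0.5; cue <- 5L; nb <- 14L
  rates <- array(rnorm(20 * nb * 1000, 8, 2), c(20, nb, 1000))
  res <- task_modulated(rates, cue, bin)
  expect_lte(mean(res$modulated), 0.015)
})

test_that("recovery time implements the three-consecutive-window rule", {
  bin <- 0.25; onset <- 9L; nb <- 29L; n_tr <- 30L
  # identical to baseline throughout: recovery at 0 s
  set.seed(96)
  base <- array(rnorm(n_tr * nb, 5, 0.5), c(n_tr, nb, 1))
  r0 <- recovery_time(base, onset, bin)
  expect_equal(r0$recovery_s, 0)
  # elevated for exactly 2 s then baseline: recovery at 2.0 s
  up <- base
  up[, onset:(onset + 7), 1] <- up[, onset:(onset + 7), 1] + 10
  r2 <- recovery_time(up, onset, bin)
  expect_equal(r2$recovery_s, 2.0)
  # permanently shifted: not recovered
  shift <- base
  shift[, onset:nb, 1] <- shift[, onset:nb, 1] + 10
  rs <- recovery_time(shift, onset, bin)
  expect_true(is.na(rs$recovery_s))
  expect_error(recovery_time(base[, 1:12, , drop = FALSE], onset, bin),
               "at least 3")
})

test_that("ramping classification has calibrated type-I error", {
  # perfect noiseless ramps ("essentially perfect fit" warning expected)
  up <- suppressWarnings(classify_ramping(seq(1, 5, length.out = 20)))
  expect_identical(up$class, "up")
  expect_lt(up$p.value, 1e-20)
  down <- suppressWarnings(classify_ramping(seq(5, 1, length.out = 20)))
  expect_identical(down$class, "down")
  expect_equal(down$slope, -up$slope, tolerance = 1e-12)
  expect_error(classify_ramping(rnorm(5)), "at least 10")
  # sign-flip symmetry on noisy data
  set.seed(97)
  y <- cumsum(rnorm(30))
  a <- classify_ramping(y); b <- classify_ramping(-y)
  expect_equal(a$slope, -b$slope, tolerance = 1e-12)
  expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
  # type-I error across 2000 i.i.d. null neurons
  set.seed(98)
  hits <- vapply(seq_len(2000), function(i)
    classify_ramping(rnorm(40))$class != "none", TRUE)
  expect_gte(mean(hits), 0.035)
  expect_lte(mean(hits), 0.065)
})

test_that("hierarchical bootstrap handles degenerate and balanced
           nesting", {
  # single session, single neuron, constant trials
  r <- hierarchical_bootstrap(rep(2.5, 8), n_iter = 50, seed = 1)
  expect_equal(r$mean, 2.5)
  expect_equal(r$sem, 0)
  # bitwise reproducibility
  set.seed(99)
  dat <- lapply(1:3, function(s) lapply(1:4, function(j) rnorm(6, s)))
  b1 <- hierarchical_bootstrap(dat, n_iter = 60, seed = 7)
  b2 <- hierarchical_bootstrap(dat, n_iter = 60, seed = 7)
  expect_identical(b1$resampled_means, b2$resampled_means)
  expect_error(hierarchical_bootstrap(list()), "empty")
  # balanced data with known grand mean: estimate within 3 sem
  mu <- 4
  set.seed(100)
  bal <- lapply(1:4, function(s) lapply(1:5, function(j) rnorm(10, mu)))
  hits <- vapply(1:20, function(sd2) {
    bb <- hierarchical_bootstrap(bal, n_iter = 100, seed = sd2)
    abs(bb$mean - mu) <= 3 * bb$sem
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate nesting reduces to the flat bootstrap", {
  set.seed(101)
  x <- rnorm(40, 1, 2)
  hb <- hierarchical_bootstrap(x, n_iter = 1000, seed = 11)
  flat <- vapply(seq_len(1000), function(b)
    mean(sample(x, length(x), replace = TRUE)), 0)
  expect_gt(ks.test(hb$resampled_means, flat)$p.value, 0.01)
})

test_that("integration statistic detects sustained shifts", {
  bin <- 0.2; onset <- 11L; nb <- 46L  # 2 s baseline, 7 s post-onset
  set.seed(102)
  # final-window mean equal to baseline: statistic 0, p near 0.5
  flat <- matrix(5, 20, nb)
  r0 <- integration_statistic(flat, bin, onset, n_iter = 200, seed = 3)
  expect_equal(r0$observed, 0)
  expect_gt(r0$p_one_sided, 0.2)
  # sustained +2 shift after onset across 50 trials
  up <- matrix(rnorm(50 * nb, 5, 0.5), 50, nb)
  up[, onset:nb] <- up[, onset:nb] + 2
  r1 <- integration_statistic(up, bin, onset, n_iter = 200, seed = 3)
  expect_gt(r1$observed, 1.5)
  expect_lt(r1$p_one_sided, 0.05)
  # sign symmetry
  r2 <- integration_statistic(-up, bin, onset, n_iter = 200, seed = 3)
  expect_equal(r2$observed, -r1$observed, tolerance = 1e-12)
  # short trials rejected
  expect_error(integration_statistic(up[, 1:30], bin, onset), "7")
})
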