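test_that("squared speed matches the map definition", {
  # identity map: fixed everywhere
  idmap <- function(H, U) H
  set.seed(61)
  states <- matrix(rnorm(20), 5)
  expect_equal(squared_speed(idmap, t(states), 0), rep(0, 4))
  # F(h) = 0.5 h at e1: q = 0.25 (no 1/2 convention)
  half <- function(H, U) 0.5 * H
  expect_equal(squared_speed(half, c(1, 0, 0), 0), 0.25)
  # GRU map: matches direct re-evaluation of the step
  mod <- tiny_model()
  h <- rnorm(6); u <- 0.3
  f1 <- generator_step(mod, h, u)
  expect_equal(squared_speed(mod, h, u), sum((f1 - h)^2),
               tolerance = 1e-12)
  expect_error(squared_speed(mod, rnorm(4), u), "dimension")
})

test_that("contractive linear map yields one fixed point at the origin", {
  half <- function(H, U) 0.5 * H
  set.seed(62)
  fps <- find_fixed_points(half, init_states = matrix(runif(40, -1, 1), 20),
                           reference_input = 0, speed_threshold = 1e-8)
  expect_equal(nrow(fps$points), 1L)
  expect_lt(max(abs(fps$points)), 1e-6)
  expect_equal(Re(fps$jacobian_eigenvalues[[1]]), c(0.5, 0.5),
               tolerance = 1e-4)
  expect_identical(fps$classification, "point")
})

test_that("zero threshold on an inexact map returns an empty set", {
  drift <- function(H, U) H + 0.05   # no exact fixed points
  expect_warning(
    fps <- find_fixed_points(drift,
                             init_states = matrix(runif(20, -1, 1), 10),
                             reference_input = 0, speed_threshold = 0),
    "empty")
  expect_equal(nrow(fps$points), 0L)
  expect_identical(fps$classification, "other")
})

test_that("slow points match a dense grid-search oracle on 2-unit maps", {
  # hand-built 2-unit fixtures on the [-1, 1]^2 square
  fixtures <- list(
    saturating_integrator = function(H, U)
      rbind(tanh(1.2 * H[1, ]), 0.4 * H[2, ]),
    contraction = function(H, U) 0.6 * H + 0.1 * tanh(H),
    rotation_decay = function(H, U) {
      A <- 0.8 * matrix(c(cos(0.3), sin(0.3), -sin(0.3), cos(0.3)), 2)
      A %*% H
    })
  grid <- as.matrix(expand.grid(seq(-1, 1, length.out = 200),
                                seq(-1, 1, length.out = 200)))
  for (nm in names(fixtures)) {
    f <- fixtures[[nm]]
    q <- squared_speed(f, grid, 0)
    # oracle: local minima of the dense grid below the threshold
    thr <- 1e-4
    oracle_pts <- grid[q <= thr, , drop = FALSE]
    set.seed(63)
    inits <- matrix(runif(60, -1, 1), 30)
    fps <- find_fixed_points(f, init_states = inits, reference_input = 0,
                             speed_threshold = thr, merge_tol = 0.02)
    expect_gt(nrow(fps$points), 0)
    for (i in seq_len(nrow(fps$points))) {
      dmin <- min(sqrt(rowSums(
        sweep(oracle_pts, 2, fps$points[i, ])^2)))
      expect_lt(dmin, 1e-2)
    }
  }
})

test_that("linearization matches linear maps and finite differences", {
  A <- matrix(c(0.7, 0.2, -0.1, 0.5), 2)
  linmap <- function(H, U) A %*% H
  lin <- linearize(linmap, c(0.1, -0.2), 0)
  expect_equal(sort(Mod(lin$values)),
               sort(Mod(eigen(A)$values)), tolerance = 1e-5)
  idmap <- function(H, U) H
  expect_equal(Re(linearize(idmap, rnorm(3), 0)$values), rep(1, 3),
               tolerance = 1e-5)
  # analytic GRU Jacobian vs central finite differences
  mod <- tiny_model()
  set.seed(64)
  h <- rnorm(6); u <- 0.2
  J <- generator_jacobian(mod, h, u)
  Jfd <- matrix(0, 6, 6)
  eps <- 1e-6
  for (j in 1:6) {
    hp <- h; hp[j] <- hp[j] + eps
    hm <- h; hm[j] <- hm[j] - eps
    Jfd[, j] <- (generator_step(mod, hp, u) -
                   generator_step(mod, hm, u)) / (2 * eps)
  }
  expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-5)
})

test_that("attractor classification follows the operational rule", {
  half <- function(H, U) 0.5 * H
  set.seed(65)
  fps <- find_fixed_points(half, init_states = matrix(runif(20, -1, 1), 10),
                           reference_input = 0, speed_threshold = 1e-8)
  expect_identical(classify_attractor(fps)$classification, "point")
  # a synthetic line of exact fixed points: F holds h1, contracts h2
  linefix <- function(H, U) rbind(H[1, ], 0.3 * H[2, ])
  inits <- cbind(seq(-1, 1, length.out = 40), runif(40, -0.5, 0.5))
  fl <- find_fixed_points(linefix, init_states = inits,
                          reference_input = 0, speed_threshold = 1e-8,
                          merge_tol = 0.02)
  expect_gte(nrow(fl$points), 5)
  expect_identical(fl$classification, "line")
  expect_gte(fl$diagnostics$pc1_var_explained, 0.9)
})

test_that("line-attractor mode equals the covariance PC1 with the sign
           convention", {
  # collinear points along e1
  pts <- cbind(seq(-2, 2, length.out = 7), 0, 0)
  fps <- structure(list(points = pts, state_scale = 1, merge_tol = 0.01),
                   class = "fixed_point_set")
  m <- line_attractor_mode(fps)
  expect_equal(abs(m), c(1, 0, 0), tolerance = 1e-10)
  expect_gte(sum(m), 0)  # positive projection onto the all-ones reference
  # two points: normalized difference
  fp2 <- structure(list(points = rbind(c(0, 0), c(1, 1)),
                        state_scale = 1, merge_tol = 0.01),
                   class = "fixed_point_set")
  expect_equal(line_attractor_mode(fp2), c(1, 1) / sqrt(2),
               tolerance = 1e-10)
  # random cloud: matches explicit covariance eigendecomposition, and is
  # invariant to point ordering
  set.seed(66)
  cloud <- matrix(rnorm(60), 20) %*% diag(c(3, 1, 0.3))
  fpc <- structure(list(points = cloud, state_scale = 1,
                        merge_tol = 0.01), class = "fixed_point_set")
  v <- line_attractor_mode(fpc)
  ev <- eigen(cov(cloud))$vectors[, 1]
  if (sum(ev) < 0) ev <- -ev
  expect_equal(v, ev, tolerance = 1e-10)
  fpp <- fpc; fpp$points <- cloud[sample(20), ]
  expect_equal(line_attractor_mode(fpp), v, tolerance = 1e-10)
  fp1 <- fpc; fp1$points <- cloud[1, , drop = FALSE]
  expect_error(line_attractor_mode(fp1), "at least 2")
})

test_that("retained speeds respect the threshold independently", {
  run <- cached_pipeline("line")
  fps <- run$fps
  expect_gt(nrow(fps$points), 0)
  q <- squared_speed(run$model, fps$points, fps$reference_input)
  expect_true(all(q <= fps$speed_threshold))
  # deduplication: pairwise distances at or above the merge tolerance
  if (nrow(fps$points) > 1) {
    dd <- as.matrix(dist(fps$points)) / fps$state_scale
    expect_true(all(dd[upper.tri(dd)] >= fps$merge_tol))
  }
  # spectra have the generator dimension
  expect_true(all(lengths(fps$jacobian_eigenvalues) ==
                    run$model$config$n_generator))
})
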