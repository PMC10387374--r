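# Fixed/slow-point analysis of the trained generator, treated as the
# discrete-time map h' = F(h, u*) under a frozen reference input u*.
# Speeds are squared one-step displacements per bin, without a 1/2 factor,
# so the retention thresholds (e.g. 3e-4 and 1e-3) apply to ||F(h)-h||^2.

gen_param_list <- function(model) {
  if (inherits(model, "lfads")) model$params else model
}

# Uniform interface over state-update maps: a fitted model (or its
# parameter list) uses the compiled GRU step with analytic gradients and
# Jacobians; a plain R function must be vectorized over state columns
# (f(H, U) with d x K matrices -> d x K) and gets central-difference
# gradients and Jacobians instead.
as_generator <- function(generator, fd_eps = 1e-5) {
  if (is.function(generator)) {
    step <- function(H, U) generator(H, U)
    qfun <- function(H, U) colSums((step(H, U) - H)^2)
    grad <- function(H, U) {
      G <- H * 0
      for (j in seq_len(nrow(H))) {
        Hp <- H; Hp[j, ] <- Hp[j, ] + fd_eps
        Hm <- H; Hm[j, ] <- Hm[j, ] - fd_eps
        G[j, ] <- (qfun(Hp, U) - qfun(Hm, U)) / (2 * fd_eps)
      }
      G
    }
    jac <- function(h, u) {
      d <- length(h)
      J <- matrix(0, d, d)
      for (j in seq_len(d)) {
        hp <- h; hp[j] <- hp[j] + fd_eps
        hm <- h; hm[j] <- hm[j] - fd_eps
        J[, j] <- (step(matrix(hp, ncol = 1), matrix(u, ncol = 1)) -
                     step(matrix(hm, ncol = 1), matrix(u, ncol = 1))) /
          (2 * fd_eps)
      }
      J
    }
    list(step = step, grad = grad, jac = jac, d = NA_integer_)
  } else {
    p <- gen_param_list(generator)
    list(step = function(H, U) gen_step_cpp(p, H, U),
         grad = function(H, U) speed_grad_cpp(p, H, U),
         jac = function(h, u) gru_jacobian(p, h, u),
         d = length(p$gen_br))
  }
}

#' Squared one-step speed of generator states
#'
#' `q(h) = ||F(h, u) - h||^2` for the generator map; zero exactly at fixed
#' points.
#'
#' @param model a fitted [lfads()] object (or its parameter list), or a
#'   vectorized state-update function `f(H, U)` operating on d x K state
#'   columns.
#' @param states numeric vector (one state) or matrix with one state per
#'   row, in generator space.
#' @param input reference input vector (length `n_input`).
#' @return numeric vector of squared speeds, one per state.
#' @export
squared_speed <- function(model, states, input) {
  gen <- as_generator(model)
  H <- if (is.matrix(states)) t(states) else matrix(states, ncol = 1)
  if (!is.na(gen$d) && nrow(H) != gen$d)
    stop("state dimension does not match the generator")
  U <- matrix(rep(as.numeric(input), ncol(H)), ncol = ncol(H))
  colSums((gen$step(H, U) - H)^2)
}

#' One generator step
#'
#' Applies the generator GRU map `F(h, u)` to a batch of states.
#'
#' @inheritParams squared_speed
#' @return matrix of next states, same orientation as `states`.
#' @export
generator_step <- function(model, states, input) {
  gen <- as_generator(model)
  vecin <- !is.matrix(states)
  H <- if (vecin) matrix(states, ncol = 1) else t(states)
  U <- matrix(rep(as.numeric(input), ncol(H)), ncol = ncol(H))
  Fh <- gen$step(H, U)
  if (vecin) as.numeric(Fh) else t(Fh)
}

#' Trial-averaged pre-cue inferred input
#'
#' The reference input used during fixed-point search: the mean of the
#' posterior-mean inferred input over all trials and all pre-cue bins.
#'
#' @param posterior an `lfads_posterior`.
#' @return numeric vector of length `n_input`.
#' @export
precue_reference_input <- function(posterior) {
  cb <- posterior$cue_bin
  if (cb < 2) stop("no pre-cue bins in this session")
  u <- posterior$input_mean[, seq_len(cb - 1L), , drop = FALSE]
  apply(u, 3, mean)
}

#' Locate fixed/slow points of the trained generator
#'
#' Minimizes the squared one-step speed `q(h) = ||F(h, u*) - h||^2` by
#' batched Adam over many initializations (states subsampled from
#' posterior generator trajectories plus Gaussian jitter, unless explicit
#' `init_states` are given), discards candidates above `speed_threshold`,
#' and merges survivors within `merge_tol` (in state units normalized by
#' the trajectory standard deviation), keeping the lowest-speed
#' representative of each cluster.  Retained points are linearized and
#' classified (see [classify_attractor()]).
#'
#' @param model a fitted [lfads()] object.
#' @param posterior an `lfads_posterior` for the same model (used for
#'   initialization and for the default reference input).
#' @param reference_input reference input vector; default: trial-averaged
#'   pre-cue inferred input, which is close to zero.
#' @param init_states optional matrix of initial states (rows).
#' @param n_inits number of initializations when subsampling.
#' @param speed_threshold retain only points with squared speed at or
#'   below this (default 3e-4).
#' @param merge_tol deduplication radius in normalized state units.
#' @param max_iters Adam iterations.
#' @param jitter_sd jitter scale as a fraction of the per-dimension state
#'   standard deviation.
#' @param newton_cutoff singular-value cutoff of the Gauss-Newton polish:
#'   directions of `J - I` with singular value below it (marginal,
#'   attractor-manifold directions) are excluded from the Newton step.
#' @param seed RNG seed for subsampling/jitter.
#' @return object of class `fixed_point_set`: `points` (matrix, one point
#'   per row), `squared_speeds`, `jacobian_eigenvalues` (list of complex
#'   spectra), `jacobians`, `reference_input`, `speed_threshold`,
#'   `merge_tol`, `state_scale`, `classification` and `diagnostics`.
#'   Empty (zero-row) sets carry `status = "no-convergence"` with a
#'   warning rather than an error.
#' @export
find_fixed_points <- function(model, posterior = NULL, reference_input = NULL,
                              init_states = NULL, n_inits = 512,
                              speed_threshold = 3e-4, merge_tol = 0.01,
                              max_iters = 1000, jitter_sd = 0.1,
                              newton_cutoff = 0.02, seed = 0) {
  gen <- as_generator(model)
  set.seed(as.integer(seed))
  if (is.null(init_states)) {
    if (missing(posterior) || is.null(posterior))
      stop("either a posterior (for initialization) or explicit ",
           "init_states is required")
    d <- if (!is.na(gen$d)) gen$d else dim(posterior$generator_states)[3L]
    G <- posterior$generator_states
    states_flat <- matrix(aperm(G, c(2, 1, 3)), ncol = d)
    dim_sd <- apply(states_flat, 2, sd)
    idx <- sample.int(nrow(states_flat), n_inits, replace = TRUE)
    init_states <- states_flat[idx, , drop = FALSE] +
      matrix(rnorm(n_inits * d), n_inits) %*% diag(jitter_sd * dim_sd, d)
    state_scale <- sqrt(mean(dim_sd^2))
  } else {
    init_states <- as.matrix(init_states)
    d <- ncol(init_states)
    state_scale <- sqrt(mean(apply(init_states, 2, var))) * 2
  }
  if (!nrow(init_states)) stop("init_states must be nonempty")
  if (!is.finite(state_scale) || state_scale == 0) state_scale <- 1
  if (is.null(reference_input)) reference_input <-
      precue_reference_input(posterior)

  H <- t(init_states)                                   # d x K
  U <- matrix(rep(as.numeric(reference_input), ncol(H)), ncol = ncol(H))
  # batched Adam on all candidate states at once
  mA <- H * 0; vA <- H * 0; b1 <- 0.9; b2 <- 0.999
  lr <- 0.05 * state_scale
  for (it in seq_len(max_iters)) {
    gr <- gen$grad(H, U)
    mA <- b1 * mA + (1 - b1) * gr
    vA <- b2 * vA + (1 - b2) * gr^2
    step <- lr * (mA / (1 - b1^it)) / (sqrt(vA / (1 - b2^it)) + 1e-12)
    H <- H - step
    if (it %% 250 == 0) lr <- lr * 0.5
  }
  # Gauss-Newton polish: solve (J - I) step = -(F(h) - h) through a
  # pseudoinverse that drops singular values below `newton_cutoff`, so
  # candidates converge onto exact fixed points in contracting directions
  # while marginal (attractor-manifold) directions are left untouched —
  # a point attractor collapses to one point, a line attractor keeps its
  # extent.
  u0 <- as.numeric(reference_input)
  for (kpt in seq_len(ncol(H))) {
    h <- H[, kpt]
    for (itn in 1:25) {
      dv <- as.numeric(gen$step(matrix(h, ncol = 1),
                                matrix(u0, ncol = 1))) - h
      if (sqrt(sum(dv^2)) < 1e-10) break
      J <- gen$jac(h, u0)
      sv <- svd(J - diag(nrow(J)))
      keep_sv <- sv$d > newton_cutoff
      if (!any(keep_sv)) break
      step <- -sv$v[, keep_sv, drop = FALSE] %*%
        (crossprod(sv$u[, keep_sv, drop = FALSE], dv) / sv$d[keep_sv])
      nstep <- sqrt(sum(step^2))
      if (nstep > 0.5 * state_scale) step <- step * 0.5 * state_scale / nstep
      h <- h + as.numeric(step)
    }
    H[, kpt] <- h
  }
  q <- colSums((gen$step(H, U) - H)^2)

  keep <- which(is.finite(q) & q <= speed_threshold)
  if (!length(keep)) {
    warning("no candidate reached the speed threshold; returning an ",
            "empty fixed-point set")
    fps <- structure(
      list(points = matrix(numeric(), 0, d), squared_speeds = numeric(),
           jacobian_eigenvalues = list(), jacobians = list(),
           reference_input = reference_input,
           speed_threshold = speed_threshold, merge_tol = merge_tol,
           state_scale = state_scale, status = "no-convergence"),
      class = "fixed_point_set")
    fps$classification <- "other"
    return(fps)
  }

  ord <- keep[order(q[keep])]
  sel <- integer()
  for (i in ord) {
    if (!length(sel)) { sel <- i; next }
    dist <- sqrt(colSums((H[, sel, drop = FALSE] - H[, i])^2)) / state_scale
    if (all(dist >= merge_tol)) sel <- c(sel, i)
  }
  pts <- t(H[, sel, drop = FALSE])
  speeds <- q[sel]

  jac <- lapply(seq_len(nrow(pts)), function(i)
    gen$jac(pts[i, ], as.numeric(reference_input)))
  eigs <- lapply(jac, function(J) eigen(J, only.values = TRUE)$values)

  fps <- structure(
    list(points = pts, squared_speeds = speeds,
         jacobian_eigenvalues = eigs, jacobians = jac,
         reference_input = reference_input,
         speed_threshold = speed_threshold, merge_tol = merge_tol,
         state_scale = state_scale, status = "ok"),
    class = "fixed_point_set")
  cl <- classify_attractor(fps)
  fps$classification <- cl$classification
  fps$diagnostics <- cl$diagnostics
  fps
}

#' Jacobian of the generator map at a state
#'
#' `dF/dh` of the state-update map at `(point, input)`: analytic for the
#' GRU generator of a fitted model, central finite differences for a
#' plain function map.
#'
#' @param model a fitted [lfads()] object, parameter list, or vectorized
#'   map function.
#' @param point state vector.
#' @param input reference input vector.
#' @return square Jacobian matrix.
#' @export
generator_jacobian <- function(model, point, input) {
  gen <- as_generator(model)
  gen$jac(as.numeric(point), as.numeric(input))
}

gru_jacobian <- function(p, point, input) {
  h <- as.numeric(point); u <- as.numeric(input)
  ar <- as.numeric(p$gen_Wr %*% u + p$gen_br + p$gen_Ur %*% h)
  az <- as.numeric(p$gen_Wz %*% u + p$gen_bz + p$gen_Uz %*% h)
  r <- 1 / (1 + exp(-ar)); z <- 1 / (1 + exp(-az))
  s <- r * h
  n <- as.numeric(tanh(p$gen_Wn %*% u + p$gen_bn + p$gen_Un %*% s))
  inner <- p$gen_Un %*% diag(r, length(h)) +
    (p$gen_Un %*% diag(h * r * (1 - r), length(h))) %*% p$gen_Ur
  diag(z, length(h)) + ((h - n) * z * (1 - z)) * p$gen_Uz +
    ((1 - z) * (1 - n^2)) * inner
}

#' Linearize the generator around a fixed point
#'
#' Full eigendecomposition of the analytic Jacobian at `(point, input)`.
#'
#' @inheritParams generator_jacobian
#' @return list with `values` (complex eigenvalues), `vectors`, and
#'   `jacobian`.
#' @export
linearize <- function(model, point, input) {
  J <- generator_jacobian(model, point, input)
  e <- eigen(J)
  list(values = e$values, vectors = e$vectors, jacobian = J)
}

#' Classify the attractor structure of a fixed-point set
#'
#' Operational rule: `"line"` iff at least `K` points are retained, the
#' first principal component of the point cloud explains at least `rho` of
#' its variance, and the median (across points) count of Jacobian
#' eigenvalues with modulus within `eps` of 1 equals exactly 1.  `"point"`
#' iff all retained points fall in a single cluster of radius at most
#' `merge_tol` (normalized units) and no eigenvalue modulus is within
#' `eps` of 1.  Anything else — including an empty set — is `"other"`.
#'
#' @param fps a `fixed_point_set`.
#' @param K minimum number of points for a line (default 5).
#' @param rho minimum PC1 variance fraction for a line (default 0.90).
#' @param eps eigenvalue-modulus tolerance around 1 (default 0.05).
#' @return list with `classification` and `diagnostics` (n_points,
#'   pc1_var_explained, near-unit eigenvalue counts, cluster radius).
#' @export
classify_attractor <- function(fps, K = 5, rho = 0.90, eps = 0.05) {
  stopifnot(inherits(fps, "fixed_point_set"))
  np <- nrow(fps$points)
  if (np == 0L)
    return(list(classification = "other",
                diagnostics = list(n_points = 0L)))
  near_unit <- vapply(fps$jacobian_eigenvalues,
                      function(ev) sum(abs(Mod(ev) - 1) <= eps), 0L)
  ctr <- colMeans(fps$points)
  radius <- if (np == 1L) 0 else
    max(sqrt(colSums((t(fps$points) - ctr)^2))) / fps$state_scale
  pc1 <- if (np >= 2L) {
    ev <- eigen(stats::cov(fps$points), symmetric = TRUE,
                only.values = TRUE)$values
    ev[1] / sum(pmax(ev, 0))
  } else NA_real_
  diag_ <- list(n_points = np, pc1_var_explained = pc1,
                near_unit_counts = near_unit, cluster_radius = radius,
                K = K, rho = rho, eps = eps)
  cls <- if (np >= K && isTRUE(pc1 >= rho) &&
             stats::median(near_unit) == 1) "line"
  else if (radius <= fps$merge_tol && all(near_unit == 0L)) "point"
  else "other"
  list(classification = cls, diagnostics = diag_)
}

#' First principal component of the fixed points (line-attractor mode)
#'
#' Unit-norm leading eigenvector of the covariance of the retained
#' points.  The sign is fixed so the mode has nonnegative inner product
#' with `sign_reference` (default: the all-ones direction in the points'
#' space, a generator-space stand-in for increasing total activity; pass
#' the pulled-back total-activity direction for the exact convention).
#'
#' @param fps a `fixed_point_set` with at least 2 points.
#' @param sign_reference direction defining the positive sense.
#' @return unit vector in the points' space.
#' @export
line_attractor_mode <- function(fps, sign_reference = NULL) {
  stopifnot(inherits(fps, "fixed_point_set"))
  if (nrow(fps$points) < 2L)
    stop("need at least 2 fixed points for a line-attractor mode")
  e <- eigen(stats::cov(fps$points), symmetric = TRUE)
  v <- e$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  if (is.null(sign_reference)) sign_reference <- rep(1, length(v))
  if (sum(v * sign_reference) < 0) v <- -v
  v
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf(
    "<fixed_point_set> %d point(s), threshold %g, classification: %s\n",
    nrow(x$points), x$speed_threshold, x$classification))
  if (nrow(x$points)) {
    cat(sprintf("  squared speeds: %.2g .. %.2g\n",
                min(x$squared_speeds), max(x$squared_speeds)))
    if (!is.null(x$diagnostics$pc1_var_explained) &&
        !is.na(x$diagnostics$pc1_var_explained))
      cat(sprintf("  PC1 variance explained: %.1f%%\n",
                  100 * x$diagnostics$pc1_var_explained))
  }
  invisible(x)
}
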