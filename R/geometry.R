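# Targeted dimensionality reduction: an ordered, Gram-Schmidt
# orthonormalized basis of hypothesis-driven modes (total activity,
# condition independent, line attractor), computed in reconstructed
# per-neuron rate space.  Generator-space states and fixed points are
# mapped into that space with map_generator_to_rate_space() before
# projection.

#' Total-activity mode
#'
#' The normalized all-ones direction in an `n_dims`-dimensional rate
#' space; its projection proxies bulk (photometry-like) population
#' activity.
#'
#' @param n_dims space dimension (>= 1).
#' @return unit vector `rep(1, n_dims) / sqrt(n_dims)`.
#' @export
total_activity_mode <- function(n_dims) {
  if (n_dims < 1) stop("n_dims must be at least 1")
  rep(1, n_dims) / sqrt(n_dims)
}

#' Condition-independent mode
#'
#' Per-neuron mean activity over a 1 s reward window minus the mean over a
#' 1 s pre-cue window, averaged across trials and bins.  Returned
#' un-normalized; normalization happens during Gram-Schmidt.
#'
#' @param data a [session_data()] object, or a trials x bins x neurons
#'   array (e.g. denoised means) via `activity`.
#' @param activity optional trials x bins x neurons array to use instead
#'   of `data$fluorescence`.
#' @param reward_start_bin 1-based bin of reward onset (default: 4 bins
#'   after the cue, matching reward collection about 0.8 s post cue).
#' @param window_s window length in seconds for both windows (default 1).
#' @return numeric per-neuron vector; a warning flags the degenerate
#'   all-zero case.
#' @export
condition_independent_mode <- function(data, activity = NULL,
                                       reward_start_bin = NULL,
                                       window_s = 1) {
  stopifnot(inherits(data, "session_data"))
  act <- activity %||% data$fluorescence
  nb <- round(window_s / data$bin_size)
  if (nb < 1) stop("window shorter than one bin")
  cb <- data$cue_bin
  if (is.null(reward_start_bin)) reward_start_bin <- cb + 4L
  rw <- reward_start_bin:(reward_start_bin + nb - 1L)
  pw <- (cb - nb):(cb - 1L)
  if (min(pw) < 1L || max(rw) > dim(act)[2L])
    stop("reward/pre-cue windows do not fit within the trial")
  v <- apply(act[, rw, , drop = FALSE], 3, mean) -
    apply(act[, pw, , drop = FALSE], 3, mean)
  if (all(abs(v) < 1e-12))
    warning("condition-independent mode is degenerate (zero vector)")
  v
}

#' Classical Gram-Schmidt orthonormalization
#'
#' Orthonormalizes the given vectors in their given order; the first
#' output is the normalized first input.  Vectors that are linearly
#' dependent within tolerance trigger an error naming the offending
#' vector.
#'
#' @param vectors list of numeric vectors, or a matrix with one vector per
#'   column.
#' @param tol relative residual-norm tolerance for the dependence check.
#' @param space_tag label recorded on the basis (`"rate_space"` or
#'   `"generator_space"`).
#' @return object of class `mode_basis`: `modes` (matrix, one unit vector
#'   per column), `space_tag`, `order`.
#' @export
gram_schmidt <- function(vectors, tol = 1e-8, space_tag = "rate_space") {
  if (is.matrix(vectors))
    vectors <- lapply(seq_len(ncol(vectors)), function(j) vectors[, j])
  k <- length(vectors)
  d <- length(vectors[[1L]])
  modes <- matrix(0, d, k)
  for (j in seq_len(k)) {
    v <- as.numeric(vectors[[j]])
    if (length(v) != d) stop("vectors must share a common dimension")
    orig_norm <- sqrt(sum(v^2))
    if (j > 1L)
      v <- v - modes[, seq_len(j - 1L), drop = FALSE] %*%
        crossprod(modes[, seq_len(j - 1L), drop = FALSE], v)
    nv <- sqrt(sum(v^2))
    if (orig_norm == 0 || nv < tol * orig_norm)
      stop(sprintf("vector %d is linearly dependent on its predecessors",
                   j))
    modes[, j] <- v / nv
  }
  structure(list(modes = modes, space_tag = space_tag, order = seq_len(k)),
            class = "mode_basis")
}

#' Project trajectories onto a mode basis
#'
#' Inner products of the last axis with each mode; trial/time axes are
#' preserved.
#'
#' @param trajectories numeric vector, matrix (time x dims) or array
#'   (trials x bins x dims).
#' @param basis a `mode_basis` (or a matrix with one mode per column).
#' @return object with the same leading axes and one trailing coordinate
#'   per mode.
#' @export
project_onto_modes <- function(trajectories, basis) {
  M <- if (inherits(basis, "mode_basis")) basis$modes else as.matrix(basis)
  d <- nrow(M)
  if (is.null(dim(trajectories))) {
    if (length(trajectories) != d) stop("dimension mismatch")
    return(as.numeric(crossprod(M, trajectories)))
  }
  dims <- dim(trajectories)
  if (dims[length(dims)] != d) stop("dimension mismatch")
  flat <- matrix(trajectories, ncol = d)
  out <- flat %*% M
  if (length(dims) == 2L) out
  else array(out, c(dims[-length(dims)], ncol(M)))
}

#' Map generator states to reconstructed rate space
#'
#' Applies the model's linear readouts (generator state -> factors ->
#' per-neuron mean), undoing the per-neuron standardization so the result
#' is in the original data units.
#'
#' @param model a fitted [lfads()] object.
#' @param states vector, matrix (states x n_generator) or array
#'   (trials x bins x n_generator).
#' @param rescale undo per-neuron standardization (default TRUE).
#' @return rates with the same leading axes and one trailing neuron axis.
#' @export
map_generator_to_rate_space <- function(model, states, rescale = TRUE) {
  p <- model$params
  W <- p$out_W %*% p$fac_W                 # neurons x n_generator
  d <- ncol(W)
  vecin <- is.null(dim(states))
  if (vecin) states <- matrix(states, 1)
  dims <- dim(states)
  if (dims[length(dims)] != d) stop("state dimension mismatch")
  flat <- matrix(states, ncol = d)
  r <- sweep(flat %*% t(W), 2, p$out_b, "+")
  if (rescale)
    r <- sweep(sweep(r, 2, model$scale, "*"), 2, model$center, "+")
  if (vecin) as.numeric(r)
  else if (length(dims) == 2L) r
  else array(r, c(dims[-length(dims)], nrow(W)))
}

#' Build the standard targeted mode basis for a fitted model
#'
#' Convenience wrapper assembling, in order: the total-activity mode, the
#' condition-independent mode of the denoised activity, and the
#' line-attractor mode (fixed points mapped to rate space, PC1), then
#' orthonormalizing with [gram_schmidt()].  Modes 2-3 are signed to
#' correlate positively with their pre-orthogonalization originals.
#'
#' @param model a fitted [lfads()] object.
#' @param posterior an `lfads_posterior` for the session.
#' @param data the [session_data()] object.
#' @param fps a `fixed_point_set` with at least 2 points.
#' @return a `mode_basis` in rate space, with the raw (pre-orthogonal)
#'   modes attached as attribute `"raw"`.
#' @export
mode_basis <- function(model, posterior, data, fps) {
  N <- model$n_neurons
  m1 <- total_activity_mode(N)
  m2 <- condition_independent_mode(data,
                                   activity = posterior$denoised_means)
  fp_rates <- map_generator_to_rate_space(model, fps$points)
  pc <- eigen(stats::cov(fp_rates), symmetric = TRUE)$vectors[, 1]
  if (sum(pc * m1) < 0) pc <- -pc
  basis <- gram_schmidt(list(m1, m2, pc), space_tag = "rate_space")
  for (j in 2:3) {
    raw <- if (j == 2) m2 else pc
    if (sum(basis$modes[, j] * raw) < 0) basis$modes[, j] <- -basis$modes[, j]
  }
  attr(basis, "raw") <- cbind(m1, m2, pc)
  basis
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("<mode_basis> %d orthonormal mode(s) in %d-dim %s\n",
              ncol(x$modes), nrow(x$modes), x$space_tag))
  invisible(x)
}
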