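#' Gaussian log-likelihood of observations under a diagonal model
#'
#' Sum over all elements of
#' \eqn{-\tfrac12[\log(2\pi v) + (y-\mu)^2/v]}.
#'
#' @param observed,mean,variance numeric arrays of equal shape; variances
#'   strictly positive.
#' @return scalar log-likelihood.
#' @export
gaussian_log_likelihood <- function(observed, mean, variance) {
  if (!identical(dim(observed) %||% length(observed),
                 dim(mean) %||% length(mean)) ||
      !identical(dim(observed) %||% length(observed),
                 dim(variance) %||% length(variance)))
    stop("observed, mean and variance must have identical shapes")
  if (any(variance <= 0)) stop("variance must be strictly positive")
  -0.5 * sum(log(2 * pi * variance) + (observed - mean)^2 / variance)
}

#' KL divergence between diagonal Gaussians
#'
#' Analytic \eqn{KL(q \| p)} for diagonal Gaussians, summed over
#' dimensions.
#'
#' @param mean_q,var_q,mean_p,var_p numeric vectors (or arrays) of equal
#'   shape; variances strictly positive.
#' @return scalar KL divergence.
#' @export
kl_diag_gaussians <- function(mean_q, var_q, mean_p, var_p) {
  if (any(var_q <= 0) || any(var_p <= 0))
    stop("variances must be strictly positive")
  0.5 * sum(log(var_p / var_q) + (var_q + (mean_q - mean_p)^2) / var_p - 1)
}

#' Causal posterior pass through a fitted model
#'
#' Runs the strictly forward encoder/controller/generator chain over a
#' session.  Every inferred quantity at bin t (inferred input, factors,
#' denoised mean, generator state) is a function only of observations at
#' bins <= t.  `mode = "mean"` propagates posterior means
#' (deterministic); `mode = "sample"` draws reparameterized samples using
#' `seed`.
#'
#' @param model a fitted [lfads()] object.
#' @param data a [session_data()] object with the model's neuron count.
#' @param mode `"mean"` or `"sample"`.
#' @param seed RNG seed for `mode = "sample"`.
#' @return list of class `lfads_posterior` with per-trial arrays
#'   `ic_mean`, `ic_var` (trials x n_generator), `inferred_inputs`
#'   (trials x bins x n_input), `factors`, `generator_states`,
#'   `denoised_means` (trials x bins x neurons, original data units) and
#'   `elbo_components` (reconstruction, kl_g0, kl_u, elbo).
#' @export
forward_causal <- function(model, data, mode = c("mean", "sample"),
                           seed = 0) {
  stopifnot(inherits(model, "lfads"), inherits(data, "session_data"))
  mode <- match.arg(mode)
  if (dim(data$fluorescence)[3L] != model$n_neurons)
    stop("data has a different neuron count than the model")
  cfg <- model$config
  Y <- prepare_tensor(data, model$center, model$scale)
  N <- dim(Y)[1L]; B <- dim(Y)[2L]; T <- dim(Y)[3L]
  set.seed(as.integer(seed))
  noise <- draw_noise(cfg, N, B, T, sample = (mode == "sample"),
                      dropout = FALSE)
  out <- lfads_pass_cpp(model$params, Y, noise, cfg$ic_prior_var, 1, 1,
                        cfg$l2_penalty, sample = (mode == "sample"),
                        want_grad = FALSE, want_outputs = TRUE)
  den <- aperm(out$denoised, c(2, 3, 1))           # trials x bins x neurons
  den <- sweep(sweep(den, 3, model$scale, "*"), 3, model$center, "+")
  structure(
    list(ic_mean = t(out$ic_mean), ic_var = t(exp(out$ic_logvar)),
         inferred_inputs = aperm(out$u, c(2, 3, 1)),
         input_mean = aperm(out$u_mean, c(2, 3, 1)),
         factors = aperm(out$factors, c(2, 3, 1)),
         generator_states = aperm(out$gstates, c(2, 3, 1)),
         g0 = t(out$g0),
         denoised_means = den,
         elbo_components = list(reconstruction = out$recon,
                                kl_g0 = out$kl_g0, kl_u = out$kl_u,
                                elbo = out$elbo),
         mode = mode, cue_bin = data$cue_bin, bin_size = data$bin_size,
         trial_type = data$trial_type),
    class = "lfads_posterior")
}

#' Posterior averaging over reparameterized samples
#'
#' Averages denoised means, inferred inputs, factors and generator states
#' over `n_samples` sampled posterior passes (the usual posterior-mean
#' protocol for this model family).  With `n_samples = 1` and
#' `mode = "mean"` it reduces to [forward_causal()].
#'
#' @param model a fitted [lfads()] object.
#' @param data a [session_data()] object.
#' @param n_samples number of posterior draws (>= 1).
#' @param seed RNG seed; draw s uses `seed + s - 1`.
#' @param mode `"sample"` (default) or `"mean"`.
#' @return an `lfads_posterior` with averaged fields.
#' @export
posterior_average <- function(model, data, n_samples = 32, seed = 0,
                              mode = c("sample", "mean")) {
  mode <- match.arg(mode)
  if (n_samples < 1) stop("n_samples must be at least 1")
  if (mode == "mean") return(forward_causal(model, data, "mean"))
  acc <- NULL
  avg_fields <- c("inferred_inputs", "input_mean", "factors",
                  "generator_states", "denoised_means")
  for (s in seq_len(n_samples)) {
    p <- forward_causal(model, data, "sample", seed = seed + s - 1L)
    if (is.null(acc)) acc <- p
    else for (f in avg_fields) acc[[f]] <- acc[[f]] + p[[f]]
  }
  for (f in avg_fields) acc[[f]] <- acc[[f]] / n_samples
  acc$n_samples <- n_samples
  acc
}

#' @export
print.lfads_posterior <- function(x, ...) {
  d <- dim(x$denoised_means)
  cat(sprintf(
    "<lfads_posterior> %d trials x %d bins x %d neurons (mode %s)\n",
    d[1], d[2], d[3], x$mode))
  e <- x$elbo_components
  cat(sprintf("  ELBO %.1f = recon %.1f - kl_g0 %.2f - kl_u %.2f\n",
              e$elbo, e$reconstruction, e$kl_g0, e$kl_u))
  invisible(x)
}
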