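#' Model configuration for the causal sequential VAE
#'
#' Network sizes and training settings.  The `"full"` preset carries the
#' analysis-scale defaults (256 generator units, 32 factors, 1 inferred
#' input dimension, 256 encoder and controller units, 200 ms bins, L2
#' penalty 1e-9, dropout keep rate 0.98); the `"small"` preset
#' (64/8/1/64/64) is sized for simulation studies and tests, where the
#' full-scale network is unnecessary.
#'
#' @param preset `"full"` or `"small"` (see above); individual arguments
#'   override the preset.
#' @param n_generator generator RNN units.
#' @param n_factors latent factors (linear readout of the generator state).
#' @param n_input dimensionality of the inferred input u(t).
#' @param n_encoder causal encoder RNN units.
#' @param n_controller controller RNN units.
#' @param bin_size bin width in seconds.
#' @param l2_penalty L2 penalty on generator/controller recurrent kernels
#'   (preset default: 1e-9 at full scale, 2e-2 at study scale, where the
#'   stronger penalty keeps unused generator units contractive).
#' @param dropout_keep_rate keep probability for dropout on encoder inputs
#'   and generator outputs (preset default: 0.98 at full scale, 0.9 at
#'   study scale).
#' @param kl_ic_weight,kl_u_weight weights on the initial-condition and
#'   inferred-input KL terms (after warm-up).
#' @param ic_prior_var prior variance of the initial generator state.
#' @param learning_rate Adam step size.
#' @param lr_decay multiplicative learning-rate decay per epoch.
#' @param max_epochs training epochs (upper bound; early stopping
#'   applies; preset default 600 full / 350 small).
#' @param kl_warmup epochs over which the KL weights ramp linearly 0 -> 1.
#' @param eval_every validation-ELBO evaluation period (epochs).
#' @param patience early-stopping patience, in evaluations.
#' @param clip_norm global gradient-norm clip.
#' @param seed integer seed controlling initialization, sampling and
#'   dropout.
#' @return an object of class `lfads_config`.
#' @export
lfads_config <- function(preset = c("full", "small"), n_generator = NULL,
                         n_factors = NULL, n_input = 1, n_encoder = NULL,
                         n_controller = NULL, bin_size = 0.2,
                         l2_penalty = NULL, dropout_keep_rate = NULL,
                         kl_ic_weight = 1, kl_u_weight = 1,
                         ic_prior_var = 0.1, learning_rate = 0.01,
                         lr_decay = 0.997, max_epochs = NULL,
                         kl_warmup = 80, eval_every = 10, patience = 15,
                         clip_norm = 50, seed = 0) {
  preset <- match.arg(preset)
  def <- if (preset == "full") c(256L, 32L, 256L, 256L)
         else c(64L, 8L, 64L, 64L)
  # at study scale a stronger recurrent penalty supplies the contraction
  # pressure that keeps unused generator units off the marginal manifold
  l2_penalty <- l2_penalty %||% if (preset == "full") 1e-9 else 2e-2
  dropout_keep_rate <- dropout_keep_rate %||%
    if (preset == "full") 0.98 else 0.9
  max_epochs <- max_epochs %||% if (preset == "full") 600 else 350
  cfg <- list(
    n_generator = as.integer(n_generator %||% def[1]),
    n_factors = as.integer(n_factors %||% def[2]),
    n_input = as.integer(n_input),
    n_encoder = as.integer(n_encoder %||% def[3]),
    n_controller = as.integer(n_controller %||% def[4]),
    bin_size = bin_size, l2_penalty = l2_penalty,
    dropout_keep_rate = dropout_keep_rate,
    kl_ic_weight = kl_ic_weight, kl_u_weight = kl_u_weight,
    ic_prior_var = ic_prior_var, learning_rate = learning_rate,
    lr_decay = lr_decay, max_epochs = as.integer(max_epochs),
    kl_warmup = as.integer(kl_warmup),
    eval_every = as.integer(eval_every), patience = as.integer(patience),
    clip_norm = clip_norm, seed = as.integer(seed), preset = preset)
  with(cfg, {
    if (any(c(n_generator, n_factors, n_input, n_encoder,
              n_controller) < 1))
      stop("all unit counts must be at least 1")
    if (dropout_keep_rate <= 0 || dropout_keep_rate > 1)
      stop("dropout_keep_rate must be in (0, 1]")
    if (l2_penalty < 0) stop("l2_penalty must be nonnegative")
  })
  class(cfg) <- "lfads_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Odd/even train/validation split
#'
#' Trials with odd 1-based session index form the training set and trials
#' with even index the validation set, order preserved within each.
#'
#' @param data a [session_data()] object with at least 2 trials.
#' @return list with elements `train` and `valid` (both `session_data`)
#'   and the index vectors `train_idx`, `valid_idx`.
#' @export
split_train_valid <- function(data) {
  stopifnot(inherits(data, "session_data"))
  n <- n_trials(data)
  if (n < 2) stop("need at least 2 trials to split")
  odd <- seq(1L, n, by = 2L)
  even <- seq(2L, n, by = 2L)
  list(train = subset_trials(data, odd), valid = subset_trials(data, even),
       train_idx = odd, valid_idx = even)
}

# ---- parameter plumbing -----------------------------------------------------

init_gru <- function(n, n_in, prefix, integrator_bias = 0) {
  sc_w <- 1 / sqrt(n_in); sc_u <- 1 / sqrt(n)
  p <- list(
    Wr = matrix(rnorm(n * n_in, 0, sc_w), n), Ur = matrix(rnorm(n * n, 0, sc_u), n),
    Wz = matrix(rnorm(n * n_in, 0, sc_w), n), Uz = matrix(rnorm(n * n, 0, sc_u), n),
    Wn = matrix(rnorm(n * n_in, 0, sc_w), n), Un = matrix(rnorm(n * n, 0, sc_u), n),
    br = numeric(n), bz = rep(integrator_bias, n), bn = numeric(n))
  names(p) <- paste0(prefix, "_", c("Wr", "Ur", "Wz", "Uz", "Wn", "Un",
                                    "br", "bz", "bn"))
  p
}

init_params <- function(cfg, n_neurons) {
  ng <- cfg$n_generator; nf <- cfg$n_factors; nu <- cfg$n_input
  ne <- cfg$n_encoder; nc <- cfg$n_controller; N <- n_neurons
  c(init_gru(ne, N, "enc"),
    init_gru(nc, ne + nf, "con"),
    # keep-gate bias +1 biases the generator toward slow dynamics
    init_gru(ng, nu, "gen", integrator_bias = 1),
    list(ic_Wm = matrix(rnorm(ng * ne, 0, 1 / sqrt(ne)), ng),
         ic_bm = numeric(ng),
         ic_Wv = matrix(0, ng, ne), ic_bv = rep(log(0.1), ng),
         u_Wm = matrix(rnorm(nu * nc, 0, 1 / sqrt(nc)), nu),
         u_bm = numeric(nu),
         u_Wv = matrix(0, nu, nc), u_bv = rep(log(0.1), nu),
         fac_W = matrix(rnorm(nf * ng, 0, 1 / sqrt(ng)), nf),
         out_W = matrix(rnorm(N * nf, 0, 1 / sqrt(nf)), N),
         out_b = numeric(N), out_logvar = numeric(N)))
}

# observations as neurons x trials x bins cube, standardized per neuron
prepare_tensor <- function(data, center, scale) {
  fl <- data$fluorescence
  y <- aperm(fl, c(3, 1, 2))
  sweep(sweep(y, 1, center, "-"), 1, scale, "/")
}

draw_noise <- function(cfg, N, B, T, sample, dropout) {
  keep <- if (dropout) cfg$dropout_keep_rate else 1
  mk_mask <- function(dims) {
    if (keep >= 1) array(1, dims)
    else array((runif(prod(dims)) < keep) / keep, dims)
  }
  list(
    eps_g0 = if (sample) matrix(rnorm(cfg$n_generator * B),
                                cfg$n_generator) else
                                  matrix(0, cfg$n_generator, B),
    eps_u = if (sample) array(rnorm(cfg$n_input * B * T),
                              c(cfg$n_input, B, T)) else
                                array(0, c(cfg$n_input, B, T)),
    mask_in = mk_mask(c(N, B, T)),
    mask_g = mk_mask(c(cfg$n_generator, B, T)))
}

# ---- fitting ----------------------------------------------------------------

#' Fit the causal sequential VAE to a session
#'
#' Trains the encoder/controller/generator network by stochastic
#' gradient ascent on the evidence lower bound (ELBO) with the
#' reparameterization trick: Gaussian emission likelihood for continuous
#' fluorescence, analytic KL terms for the initial condition and the
#' inferred inputs with a linear warm-up ramp, L2 penalty on recurrent
#' kernels, inverted dropout on encoder inputs and generator outputs, Adam
#' with gradient clipping, and early stopping on the validation ELBO.
#' Trials are split odd/even into training and validation sets.
#'
#' Observations are standardized per neuron before fitting; the scaling is
#' stored on the model and undone by [predict.lfads()].
#'
#' @param data a [session_data()] object (>= 2 trials, per-neuron variance
#'   positive).
#' @param config an [lfads_config()].
#' @param verbose print progress every few epochs.
#' @return an object of class `lfads` with elements `params` (best
#'   parameters by validation ELBO), `config`, `center`/`scale`,
#'   `training_curve` (per-epoch data frame), `valid_curve`, and
#'   `n_neurons`.
#' @export
lfads <- function(data, config = lfads_config("small"), verbose = FALSE) {
  stopifnot(inherits(data, "session_data"), inherits(config, "lfads_config"))
  cfg <- config
  fl <- data$fluorescence
  N <- dim(fl)[3L]
  center <- apply(fl, 3L, mean)
  scale <- apply(fl, 3L, sd)
  if (any(scale <= 0)) stop("every neuron must have positive variance")

  sp <- split_train_valid(data)
  Ytr <- prepare_tensor(sp$train, center, scale)
  Yva <- prepare_tensor(sp$valid, center, scale)
  Btr <- dim(Ytr)[2L]; T <- dim(Ytr)[3L]

  set.seed(cfg$seed)
  params <- init_params(cfg, N)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  lr <- cfg$learning_rate

  ones_noise <- draw_noise(cfg, N, dim(Yva)[2L], T, sample = FALSE,
                           dropout = FALSE)
  curve <- data.frame(epoch = integer(), loss = numeric(),
                      recon = numeric(), kl_g0 = numeric(),
                      kl_u = numeric(), kl_weight = numeric())
  vcurve <- data.frame(epoch = integer(), elbo = numeric())
  best <- list(elbo = -Inf, params = params, epoch = 0L)
  stall <- 0L

  for (ep in seq_len(cfg$max_epochs)) {
    w <- min(1, ep / max(1L, cfg$kl_warmup))
    noise <- draw_noise(cfg, N, Btr, T, sample = TRUE,
                        dropout = cfg$dropout_keep_rate < 1)
    out <- lfads_pass_cpp(params, Ytr, noise, cfg$ic_prior_var,
                          w * cfg$kl_ic_weight, w * cfg$kl_u_weight,
                          cfg$l2_penalty, sample = TRUE, want_grad = TRUE,
                          want_outputs = FALSE)
    if (!is.finite(out$loss))
      stop(sprintf("training loss diverged (non-finite) at epoch %d", ep))
    g <- out$grad
    gn <- sqrt(sum(vapply(g, function(x) sum(x^2), 0)))
    cl <- if (gn > cfg$clip_norm) cfg$clip_norm / gn else 1
    t_ad <- ep
    for (nm in names(params)) {
      gi <- g[[nm]] * cl
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gi
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gi^2
      mhat <- m[[nm]] / (1 - b1^t_ad)
      vhat <- v[[nm]] / (1 - b2^t_ad)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + epsA)
    }
    lr <- lr * cfg$lr_decay
    curve[nrow(curve) + 1L, ] <- list(ep, out$loss, out$recon, out$kl_g0,
                                      out$kl_u, w)

    if (ep %% cfg$eval_every == 0L || ep == cfg$max_epochs) {
      vo <- lfads_pass_cpp(params, Yva, ones_noise, cfg$ic_prior_var, 1, 1,
                           cfg$l2_penalty, sample = FALSE,
                           want_grad = FALSE, want_outputs = FALSE)
      vcurve[nrow(vcurve) + 1L, ] <- list(ep, vo$elbo)
      if (vo$elbo > best$elbo && w >= 1) {
        best <- list(elbo = vo$elbo, params = params, epoch = ep)
        stall <- 0L
      } else if (w >= 1) stall <- stall + 1L
      if (verbose)
        message(sprintf(
          "epoch %4d  train loss %.4f  valid ELBO %.1f%s", ep, out$loss,
          vo$elbo, if (best$epoch == ep) "  *" else ""))
      if (stall >= cfg$patience) break
    }
  }
  if (!is.finite(best$elbo)) best <- list(elbo = vcurve$elbo[nrow(vcurve)],
                                          params = params, epoch = ep)

  structure(
    list(params = best$params, config = cfg, center = center, scale = scale,
         n_neurons = N, training_curve = curve, valid_curve = vcurve,
         best_epoch = best$epoch, best_valid_elbo = best$elbo,
         bin_size = data$bin_size, cue_bin = data$cue_bin),
    class = "lfads")
}

#' @export
print.lfads <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<lfads> %d neurons | generator %d, factors %d, input dim %d\n",
    x$n_neurons, cfg$n_generator, cfg$n_factors, cfg$n_input))
  cat(sprintf("  trained %d epochs; best validation ELBO %.1f (epoch %d)\n",
              nrow(x$training_curve), x$best_valid_elbo, x$best_epoch))
  invisible(x)
}

#' @export
summary.lfads <- function(object, ...) {
  tc <- object$training_curve
  out <- list(config = object$config,
              n_epochs = nrow(tc),
              first_loss = tc$loss[1L], final_loss = tc$loss[nrow(tc)],
              best_epoch = object$best_epoch,
              best_valid_elbo = object$best_valid_elbo,
              emission_sd_range = range(exp(0.5 *
                object$params$out_logvar) * object$scale))
  class(out) <- "summary.lfads"
  out
}

#' @export
print.summary.lfads <- function(x, ...) {
  cat(sprintf(
    "causal sequential VAE: %d epochs, loss %.4f -> %.4f\n",
    x$n_epochs, x$first_loss, x$final_loss))
  cat(sprintf("best validation ELBO %.1f at epoch %d\n",
              x$best_valid_elbo, x$best_epoch))
  cat(sprintf("per-neuron emission sd (data units): %.3g .. %.3g\n",
              x$emission_sd_range[1], x$emission_sd_range[2]))
  invisible(x)
}

#' @export
coef.lfads <- function(object, ...) object$params

#' @export
plot.lfads <- function(x, ...) {
  tc <- x$training_curve
  graphics::plot(tc$epoch, tc$loss, type = "l", xlab = "epoch",
                 ylab = "training loss (per trial-bin)", ...)
  vc <- x$valid_curve
  if (nrow(vc)) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(vc$epoch, -vc$elbo, type = "l", col = 2, axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(4, col.axis = 2)
    graphics::legend("topright", c("train loss", "-valid ELBO"),
                     col = c(1, 2), lty = 1, bty = "n")
  }
  invisible(x)
}

#' @export
residuals.lfads <- function(object, data, ...) {
  post <- forward_causal(object, data, mode = "mean")
  data$fluorescence - post$denoised_means
}

#' @export
predict.lfads <- function(object, newdata,
                          type = c("denoised", "factors", "inputs"),
                          mode = c("mean", "sample"), seed = 0, ...) {
  type <- match.arg(type)
  post <- forward_causal(object, newdata, mode = match.arg(mode),
                         seed = seed)
  switch(type, denoised = post$denoised_means, factors = post$factors,
         inputs = post$inferred_inputs)
}
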