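#' Construct a ground-truth latent attractor system
#'
#' Builds a discrete-time linear latent dynamical system
#' \eqn{x_{t+1} = A x_t + p_t} with a linear readout to neurons, a calcium
#' kernel and Gaussian emission noise.  With `kind = "line"` the update
#' matrix has exactly one eigenvalue equal to 1 whose eigenvector
#' (`integration_mode`) integrates any input component aligned with it —
#' the selection-vector mechanism of a line attractor.  With
#' `kind = "point"` all eigenvalue moduli are at most `1 - slow_margin`, so
#' every perturbation decays back to the origin.
#'
#' The system carries three input pulses with fixed per-bin amplitude
#' schedules relative to the cue bin: a cue pulse (both trial types, bins
#' cue..cue+1), and reward-outcome pulses at bins cue+4..cue+5 (about 1 s
#' after the cue, when reward is collected).  By default the rewarded pulse
#' has alignment 0.9 with `integration_mode` while the unrewarded pulse is
#' orthogonal to it, so only rewards are integrated.
#'
#' @param kind `"line"` or `"point"`.
#' @param n_latent latent dimension (>= 2).
#' @param n_neurons number of readout neurons (>= 1).
#' @param seed integer RNG seed; the construction is deterministic given it.
#' @param noise_sd per-neuron Gaussian emission standard deviation.
#' @param calcium_tau_decay calcium-indicator decay constant in seconds.
#' @param bin_size bin width in seconds.
#' @param slow_margin margin `delta`: non-integrating eigenvalue moduli are
#'   at most `1 - slow_margin`.
#' @param reward_alignment cosine between the rewarded pulse direction and
#'   `integration_mode` (line systems).
#' @param reward_amplitude per-bin amplitude of the rewarded pulse.
#' @param unrewarded_amplitude per-bin amplitude of the unrewarded pulse.
#' @param cue_amplitude per-bin amplitude of the cue pulse.
#' @return an object of class `gt_system`; a plain list whose fields
#'   (`update_matrix`, `integration_mode`, `input_rewarded`,
#'   `input_unrewarded`, `input_cue`, `readout`, `rate_offset`, ...) may be
#'   modified before simulation.
#' @export
make_system <- function(kind = c("line", "point"), n_latent = 4,
                        n_neurons = 30, seed = 0, noise_sd = 0.2,
                        calcium_tau_decay = 0.4, bin_size = 0.2,
                        slow_margin = 0.1, reward_alignment = 0.9,
                        reward_amplitude = 0.25,
                        unrewarded_amplitude = 0.25, cue_amplitude = 0.4) {
  kind <- match.arg(kind)
  if (n_latent < 2) stop("n_latent must be at least 2")
  if (n_neurons < 1) stop("n_neurons must be at least 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (calcium_tau_decay <= 0) stop("calcium_tau_decay must be positive")
  set.seed(as.integer(seed))

  # random orthonormal latent basis; symmetric update matrix A = Q L Q'
  Q <- qr.Q(qr(matrix(rnorm(n_latent^2), n_latent)))
  lam <- runif(n_latent, 0.3, 1 - slow_margin)
  lam[1] <- if (kind == "line") 1 else 1 - slow_margin - 0.1
  A <- Q %*% diag(lam) %*% t(Q)
  mode <- Q[, 1]

  perp <- function(j) Q[, j]  # orthonormal complements of the mode
  rew_dir <- reward_alignment * mode +
    sqrt(max(0, 1 - reward_alignment^2)) * perp(2)
  unr_dir <- perp(3)
  cue_dir <- perp(min(4L, n_latent))

  pulse <- function(direction, offsets, amplitude)
    list(direction = direction, offsets = as.integer(offsets),
         amplitude = amplitude)

  # readout: loadings on the integration mode are positive so that bulk
  # (photometry-like) activity increases with integrated reward
  load_mode <- abs(rnorm(n_neurons, 1, 0.3))
  other <- matrix(rnorm(n_neurons * (n_latent - 1), 0, 0.5),
                  n_neurons, n_latent - 1)
  readout <- (cbind(load_mode, other) %*% t(Q)) / sqrt(n_latent)

  structure(
    list(kind = kind, n_latent = n_latent, n_neurons = n_neurons,
         update_matrix = A, integration_mode = mode,
         input_rewarded = pulse(rew_dir, c(4L, 5L), reward_amplitude),
         input_unrewarded = pulse(unr_dir, c(4L, 5L), unrewarded_amplitude),
         input_cue = pulse(cue_dir, c(0L, 1L), cue_amplitude),
         readout = readout,
         rate_offset = abs(rnorm(n_neurons, 1, 0.2)),
         calcium_tau_decay = calcium_tau_decay, noise_sd = noise_sd,
         bin_size = bin_size, slow_margin = slow_margin, seed = seed),
    class = "gt_system")
}

#' Validate the invariants of a ground-truth system
#'
#' Checks the eigenstructure implied by `kind` (exactly one unit eigenvalue
#' with all others inside `1 - slow_margin` for line systems; spectral
#' radius below `1 - slow_margin` for point systems), that
#' `integration_mode` is a unit eigenvector for eigenvalue 1 when
#' `kind = "line"`, and positivity constraints.
#'
#' @param system a `gt_system`.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_system <- function(system) {
  stopifnot(inherits(system, "gt_system"))
  ev <- Mod(eigen(system$update_matrix, only.values = TRUE)$values)
  margin <- system$slow_margin
  if (system$kind == "line") {
    if (sum(abs(ev - 1) < 1e-10) != 1L)
      stop("line system must have exactly one unit eigenvalue")
    if (any(ev[abs(ev - 1) >= 1e-10] > 1 - margin + 1e-10))
      stop("non-integrating eigenvalues exceed the slow margin")
    m <- system$integration_mode
    if (abs(sqrt(sum(m^2)) - 1) > 1e-8)
      stop("integration_mode must have unit norm")
    if (max(abs(system$update_matrix %*% m - m)) > 1e-8)
      stop("integration_mode is not an eigenvector for eigenvalue 1")
  } else {
    if (any(ev > 1 - margin + 1e-10))
      stop("point system spectral radius exceeds 1 - slow_margin")
  }
  if (system$calcium_tau_decay <= 0 || system$bin_size <= 0 ||
      system$noise_sd < 0)
    stop("calcium_tau_decay and bin_size must be positive, noise_sd >= 0")
  invisible(TRUE)
}

#' @export
print.gt_system <- function(x, ...) {
  cat(sprintf("<gt_system> %s attractor, %d latents -> %d neurons\n",
              x$kind, x$n_latent, x$n_neurons))
  ev <- sort(Mod(eigen(x$update_matrix, only.values = TRUE)$values),
             decreasing = TRUE)
  cat("  |eigenvalues|:", paste(sprintf("%.3f", ev), collapse = " "), "\n")
  invisible(x)
}

#' Causal exponential calcium-kernel convolution
#'
#' Applies the single-exponential indicator kernel as a causal recursive
#' filter with unit DC gain: `y[t] = phi * y[t-1] + (1 - phi) * x[t]` with
#' `phi = exp(-bin_size / tau_decay)`, initialized at steady state for the
#' first sample (`y[1] = x[1]`), so a constant input is reproduced exactly
#' and an impulse on a flat background decays geometrically with ratio
#' `phi`.
#'
#' @param rates numeric vector or time x neurons matrix.
#' @param tau_decay decay constant in seconds (> 0).
#' @param bin_size bin width in seconds (> 0).
#' @return filtered object of the same shape.
#' @export
calcium_convolve <- function(rates, tau_decay, bin_size) {
  if (!is.numeric(tau_decay) || tau_decay <= 0)
    stop("tau_decay must be positive")
  if (!is.numeric(bin_size) || bin_size <= 0)
    stop("bin_size must be positive")
  phi <- exp(-bin_size / tau_decay)
  one <- function(x) {
    if (length(x) == 0L) return(x)
    inp <- c(x[1L], (1 - phi) * x[-1L])
    as.numeric(stats::filter(inp, phi, method = "recursive"))
  }
  if (is.matrix(rates)) apply(rates, 2L, one) else one(rates)
}

#' Simulate a trial-structured session from a ground-truth system
#'
#' Trial types are drawn i.i.d. Bernoulli(`p_reward`).  Within each trial
#' the latent state evolves as `x[t+1] = A x[t] + pulses[t]`; the state of
#' trial k+1 continues from trial k's final state unless
#' `reset_between_trials` is set, so integrated reward evidence ramps
#' across the session.  Rates are `readout %*% x + rate_offset`, convolved
#' with the calcium kernel over the concatenated session, with i.i.d.
#' Gaussian noise added per bin and neuron.
#'
#' @param system a `gt_system`.
#' @param n_trials number of trials (>= 1).
#' @param p_reward reward probability in \[0, 1\].
#' @param bins_per_trial bins per trial (default 40, i.e. 8 s at 200 ms).
#' @param seed RNG seed.
#' @param cue_bin 1-based cue-onset bin (default 6: 1 s pre-cue period).
#' @param reset_between_trials reset the latent state to zero at each trial
#'   start (off by default).
#' @param x0 initial latent state (default zero).
#' @return a [session_data()] object with attribute `"latents"`
#'   (trials x bins x n_latent ground-truth latent trajectory).
#' @export
simulate_session <- function(system, n_trials, p_reward = 0.85,
                             bins_per_trial = 40, seed = 0, cue_bin = 6,
                             reset_between_trials = FALSE, x0 = NULL) {
  stopifnot(inherits(system, "gt_system"))
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (p_reward < 0 || p_reward > 1) stop("p_reward must be in [0, 1]")
  set.seed(as.integer(seed))
  d <- system$n_latent; N <- system$n_neurons; T <- as.integer(bins_per_trial)
  types <- ifelse(rbinom(n_trials, 1L, p_reward) == 1L,
                  "rewarded", "unrewarded")

  pulse_sched <- function(type) {
    # bins x d matrix of pulse input for one trial
    P <- matrix(0, T, d)
    add <- function(p) {
      b <- cue_bin + p$offsets
      b <- b[b >= 1 & b <= T]
      for (bb in b) P[bb, ] <<- P[bb, ] + p$amplitude * p$direction
    }
    add(system$input_cue)
    add(if (type == "rewarded") system$input_rewarded
        else system$input_unrewarded)
    P
  }

  x <- if (is.null(x0)) numeric(d) else as.numeric(x0)
  lat <- array(0, c(n_trials, T, d))
  for (k in seq_len(n_trials)) {
    if (reset_between_trials) x <- numeric(d)
    P <- pulse_sched(types[k])
    for (t in seq_len(T)) {
      x <- as.numeric(system$update_matrix %*% x) + P[t, ]
      lat[k, t, ] <- x
    }
  }

  # rates over the concatenated session, calcium-filtered, plus noise
  lat_flat <- matrix(aperm(lat, c(2, 1, 3)), n_trials * T, d)  # time x d
  rates <- lat_flat %*% t(system$readout) +
    matrix(system$rate_offset, n_trials * T, N, byrow = TRUE)
  fl_clean <- calcium_convolve(rates, system$calcium_tau_decay,
                               system$bin_size)
  fl <- fl_clean
  if (system$noise_sd > 0)
    fl <- fl + matrix(rnorm(length(fl), 0, system$noise_sd), nrow(fl))
  fl3 <- aperm(array(fl, c(T, n_trials, N)), c(2, 1, 3))

  out <- session_data(fl3, types, cue_bin, system$bin_size,
                      session_id = sprintf("sim-%s-seed%d", system$kind,
                                           as.integer(seed)))
  attr(out, "latents") <- lat
  attr(out, "noiseless_rates") <- aperm(array(fl_clean, c(T, n_trials, N)),
                                        c(2, 1, 3))
  out
}
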