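# In silico experiments: run the trained generator forward as a
# standalone dynamical system under condition-averaged inferred inputs and
# Bernoulli-sampled reward schedules, and titrate reward probability.

#' Condition-averaged inferred inputs
#'
#' Trial-averaged posterior-mean inferred input of rewarded and unrewarded
#' trials, restricted to the window from 1 s before to 3 s after cue
#' onset.
#'
#' @param posterior an `lfads_posterior`.
#' @param relaxation_s inter-trial relaxation with zero input, in seconds
#'   (default 1).
#' @return object of class `input_library`: `rewarded_input` and
#'   `unrewarded_input` (bins x n_input matrices), `cue_offset_bins`
#'   (bins from window start to cue onset), `relaxation_bins`, `bin_size`.
#' @export
condition_averaged_inputs <- function(posterior, relaxation_s = 1) {
  bs <- posterior$bin_size
  cb <- posterior$cue_bin
  pre <- round(1 / bs); post <- round(3 / bs)
  win <- (cb - pre):(cb + post - 1L)
  if (min(win) < 1L || max(win) > dim(posterior$input_mean)[2L])
    stop("the -1 s .. +3 s window does not fit within the trial")
  one <- function(type) {
    idx <- which(posterior$trial_type == type)
    if (!length(idx)) stop("no trials of type '", type, "' in the session")
    u <- posterior$input_mean[idx, win, , drop = FALSE]
    matrix(apply(u, c(2, 3), mean), length(win))
  }
  structure(
    list(rewarded_input = one("rewarded"),
         unrewarded_input = one("unrewarded"),
         # the model's neutral tonic input: "zero effective input" for
         # inter-trial relaxation means zero deviation from this level
         neutral_input = precue_reference_input(posterior),
         cue_offset_bins = pre, relaxation_bins = round(relaxation_s / bs),
         bin_size = bs),
    class = "input_library")
}

#' Run one in silico session on the trained generator
#'
#' Iterates trials: draw the trial type from Bernoulli(`p_reward`), roll
#' the generator through the corresponding 4 s condition-averaged input,
#' then through `relaxation_bins` bins of zero effective input (the
#' session's neutral tonic input level, close to zero).  The session
#' stops after `max_rewarded` rewarded trials (including that trial's
#' relaxation) or at `trial_cap` trials, whichever comes first.  The
#' photometry proxy is the rate-space trajectory projected onto the
#' total-activity mode.
#'
#' @param model a fitted [lfads()] object.
#' @param lib an `input_library` from [condition_averaged_inputs()].
#' @param p_reward reward probability in \[0, 1\].
#' @param init_state generator-space initial state vector.
#' @param seed RNG seed for the Bernoulli draws.
#' @param max_rewarded stop after this many rewarded trials (default 10).
#' @param trial_cap hard cap on total trials (default 40) so sessions with
#'   small `p_reward` terminate; hitting the cap raises a warning when
#'   `p_reward` is 0.
#' @return list: `trajectory` (bins x n_generator), `photometry_proxy`
#'   (per bin), `trial_type`, `reward_means` (per rewarded trial, mean
#'   proxy over the 1 s reward window), `n_rewarded`.
#' @export
run_insilico_session <- function(model, lib, p_reward, init_state,
                                 seed = 0, max_rewarded = 10,
                                 trial_cap = 40) {
  stopifnot(inherits(lib, "input_library"))
  if (p_reward < 0 || p_reward > 1) stop("p_reward must be in [0, 1]")
  set.seed(as.integer(seed))
  p <- gen_param_list(model)
  N <- model$n_neurons
  tam <- total_activity_mode(N)
  Tin <- nrow(lib$rewarded_input)
  neutral <- lib$neutral_input %||% rep(0, ncol(lib$rewarded_input))
  relax <- matrix(neutral, lib$relaxation_bins,
                  ncol(lib$rewarded_input), byrow = TRUE)
  # reward collected ~0.8 s after cue; proxy averaged over the following 1 s
  rw0 <- lib$cue_offset_bins + round(0.8 / lib$bin_size)
  rw <- rw0:(rw0 + round(1 / lib$bin_size) - 1L)

  h <- as.numeric(init_state)
  traj <- list(); types <- character(); reward_means <- numeric()
  n_rew <- 0L; k <- 0L
  while (n_rew < max_rewarded && k < trial_cap) {
    k <- k + 1L
    rewarded <- rbinom(1L, 1L, p_reward) == 1L
    types <- c(types, if (rewarded) "rewarded" else "unrewarded")
    U <- rbind(if (rewarded) lib$rewarded_input else lib$unrewarded_input,
               relax)
    tr <- matrix(0, nrow(U), length(h))
    for (t in seq_len(nrow(U))) {
      h <- generator_step(p, h, U[t, ])
      tr[t, ] <- h
    }
    traj[[k]] <- tr
    if (rewarded) {
      n_rew <- n_rew + 1L
      rates <- map_generator_to_rate_space(model, tr[rw, , drop = FALSE])
      reward_means <- c(reward_means, mean(rates %*% tam))
    }
  }
  if (k == trial_cap && n_rew < max_rewarded && p_reward == 0)
    warning("trial cap reached with no rewarded-trial stop")
  trajectory <- do.call(rbind, traj)
  proxy <- as.numeric(
    map_generator_to_rate_space(model, trajectory) %*% tam)
  list(trajectory = trajectory, photometry_proxy = proxy,
       trial_type = types, reward_means = reward_means, n_rewarded = n_rew)
}

#' Reward-probability titration of the trained generator
#'
#' For each reward probability, simulates `n_sessions` in silico sessions
#' with initial conditions sampled uniformly along the identified line
#' attractor (the segment spanned by the retained fixed points), and
#' averages the photometry proxy of the n-th rewarded trial across
#' sessions.  The accumulation slope is the least-squares slope of that
#' mean curve against the rewarded-trial index.
#'
#' @param model a fitted [lfads()] object.
#' @param lib an `input_library`.
#' @param fps a `fixed_point_set`; required to sample initial conditions
#'   on the attractor (error advising an explicit `init_states` if it has
#'   fewer than 2 points).
#' @param probs reward probabilities (default `c(0.5, 0.8, 1.0)`).
#' @param n_sessions sessions per probability (default 1000).
#' @param seed master RNG seed.
#' @param init_states optional matrix of initial states (rows), sampled
#'   from instead of the attractor segment.
#' @param ... passed to [run_insilico_session()].
#' @return object of class `titration`: `curves` (probability x
#'   rewarded-trial-index matrix of mean proxies), `slopes`, `slope_se`
#'   (standard error of the slope from across-session variability),
#'   `probs`, `n_sessions`.
#' @export
titrate <- function(model, lib, fps, probs = c(0.5, 0.8, 1.0),
                    n_sessions = 1000, seed = 0, init_states = NULL,
                    ...) {
  if (is.null(init_states)) {
    if (!inherits(fps, "fixed_point_set") || nrow(fps$points) < 2L)
      stop("no line attractor available to sample initial conditions ",
           "from; supply init_states explicitly")
    mode <- line_attractor_mode(fps)
    ctr <- colMeans(fps$points)
    proj <- as.numeric(t(t(fps$points) - ctr) %*% mode)
    seg <- range(proj)
  }
  set.seed(as.integer(seed))
  nmax <- list(...)$max_rewarded %||% 10
  curves <- matrix(NA_real_, length(probs), nmax,
                   dimnames = list(paste0("p", probs), NULL))
  slopes <- slope_se <- numeric(length(probs))
  for (i in seq_along(probs)) {
    per_session <- matrix(NA_real_, n_sessions, nmax)
    sess_slopes <- rep(NA_real_, n_sessions)
    for (s in seq_len(n_sessions)) {
      init <- if (is.null(init_states)) {
        ctr + runif(1, seg[1], seg[2]) * mode
      } else {
        init_states[sample.int(nrow(init_states), 1L), ]
      }
      run <- run_insilico_session(model, lib, probs[i], init,
                                  seed = sample.int(2^30, 1L), ...)
      if (length(run$reward_means))
        per_session[s, seq_along(run$reward_means)] <- run$reward_means
      if (length(run$reward_means) >= 2L) {
        ii <- seq_along(run$reward_means)
        sess_slopes[s] <- coef(lm(run$reward_means ~ ii))[2L]
      }
    }
    curves[i, ] <- colMeans(per_session, na.rm = TRUE)
    idx <- which(!is.na(curves[i, ]))
    slopes[i] <- coef(lm(curves[i, idx] ~ idx))[2L]
    ok <- !is.na(sess_slopes)
    slope_se[i] <- sd(sess_slopes[ok]) / sqrt(sum(ok))
  }
  structure(list(curves = curves, slopes = slopes, slope_se = slope_se,
                 probs = probs, n_sessions = n_sessions),
            class = "titration")
}

#' @export
print.titration <- function(x, ...) {
  cat("<titration> accumulation slopes (proxy units per rewarded trial):\n")
  for (i in seq_along(x$probs))
    cat(sprintf("  p_reward = %.2f : slope %+.4g (se %.2g)\n",
                x$probs[i], x$slopes[i], x$slope_se[i]))
  invisible(x)
}

#' @export
plot.titration <- function(x, ...) {
  graphics::matplot(t(x$curves), type = "b", pch = 16, lty = 1,
                    xlab = "n-th rewarded trial",
                    ylab = "mean photometry proxy", ...)
  graphics::legend("topleft", legend = sprintf("p = %.2f", x$probs),
                   col = seq_along(x$probs), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate from a fitted model
#'
#' [simulate()] method: rolls the trained generator as a standalone
#' dynamical system through one in silico session (see
#' [run_insilico_session()]).
#'
#' @param object a fitted [lfads()] object.
#' @param nsim number of sessions.
#' @param seed RNG seed.
#' @param lib an `input_library`.
#' @param p_reward reward probability.
#' @param init_state generator-space initial state.
#' @param ... passed to [run_insilico_session()].
#' @return a list of session rollouts (length `nsim`).
#' @export
simulate.lfads <- function(object, nsim = 1, seed = 0, lib, p_reward,
                           init_state, ...) {
  lapply(seq_len(nsim), function(s)
    run_insilico_session(object, lib, p_reward, init_state,
                         seed = seed + s - 1L, ...))
}
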