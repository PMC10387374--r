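# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; heavyweight fits are memoized so
# several test files can share one trained model per attractor kind.

.fit_cache <- new.env(parent = emptyenv())

# study-scale reference pipeline (30 neurons, 120 trials, small config)
cached_pipeline <- function(kind, seed = 1) {
  key <- paste0(kind, "-", seed)
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  sys <- make_system(kind, seed = seed)
  ses <- simulate_session(sys, 120, seed = seed)
  mod <- lfads(ses, lfads_config("small", seed = seed))
  post <- forward_causal(mod, ses, "mean")
  fps <- find_fixed_points(mod, post, seed = seed)
  .fit_cache[[key]] <- list(system = sys, session = ses, model = mod,
                            posterior = post, fps = fps)
  .fit_cache[[key]]
}

# tiny untrained model for fast structural tests
tiny_model <- function(N = 5, seed = 7, n_gen = 6, n_fac = 3, n_enc = 4,
                       n_con = 4, n_input = 1) {
  cfg <- lfads_config("small", n_generator = n_gen, n_factors = n_fac,
                      n_encoder = n_enc, n_controller = n_con,
                      n_input = n_input, seed = seed)
  set.seed(seed)
  structure(list(params = init_params_for_test(cfg, N), config = cfg,
                 center = rep(0, N), scale = rep(1, N), n_neurons = N,
                 bin_size = 0.2, cue_bin = 3L),
            class = "lfads")
}

init_params_for_test <- function(cfg, N) {
  getFromNamespace("init_params", "calfads")(cfg, N)
}

random_session <- function(n_trials = 6, n_bins = 10, N = 5, seed = 1,
                           cue_bin = 3) {
  set.seed(seed)
  session_data(array(rnorm(n_trials * n_bins * N),
                     c(n_trials, n_bins, N)),
               rep(c("rewarded", "unrewarded"), length.out = n_trials),
               cue_bin = cue_bin)
}

# O(T^2) convolution-sum oracle for the causal calcium kernel
convolve_oracle <- function(x, tau, bin) {
  phi <- exp(-bin / tau)
  T <- length(x)
  y <- numeric(T)
  for (t in seq_len(T)) {
    y[t] <- phi^(t - 1) * x[1]
    if (t > 1) for (j in 2:t) y[t] <- y[t] + (1 - phi) * phi^(t - j) * x[j]
  }
  y
}

# full sign-enumeration oracle for the Wilcoxon signed-rank null
wilcoxon_enum_oracle <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% r)
  p_le <- mean(W <= V + 1e-9)
  p_ge <- mean(W >= V - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge, less = p_le)
}

# synthetic dual-channel photometry: shared slow artifact in both
# channels, calcium-like transients only in the 490 nm signal
make_record <- function(n_s = 30, fs = 1017, seed = 1,
                        with_transients = TRUE) {
  set.seed(seed)
  n <- round(n_s * fs)
  t <- (seq_len(n) - 1) / fs
  artifact <- 3 * exp(-t / 20) + 0.5 * sin(2 * pi * 0.05 * t)
  transient <- numeric(n)
  if (with_transients) {
    onsets <- seq(2, n_s - 2, by = 3)
    for (o in onsets) {
      idx <- which(t >= o & t < o + 2)
      transient[idx] <- transient[idx] + 2 * exp(-(t[idx] - o) / 0.4)
    }
  }
  list(t = t, artifact = artifact, transient = transient,
       record = photometry_record(
         signal_490 = 100 + 1.8 * artifact + transient +
           rnorm(n, 0, 0.02),
         control_405 = 40 + artifact + rnorm(n, 0, 0.02), fs = fs))
}

# definitional O(m^2) Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(k) m * p[o[k]] / k, 0)
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}
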