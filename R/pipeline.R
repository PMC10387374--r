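# One-call reproducible pipeline: simulate -> fit -> posterior ->
# fixed points -> mode basis -> in silico titration, with per-stage seeds
# fanned out from a single master seed.

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes the standard stage chain with a single master seed: the
#' master seed deterministically spawns one sub-seed per stage
#' (simulation, fitting, posterior sampling, fixed-point search,
#' titration), so any stage can be re-run independently yet
#' reproducibly.  Stages not requested are skipped.
#'
#' @param kind ground-truth attractor kind, `"line"` or `"point"`.
#' @param seed master seed.
#' @param n_trials,p_reward,n_neurons simulation settings.
#' @param config an [lfads_config()] (default: the `"small"` preset with
#'   the fitting sub-seed).
#' @param stages character vector among `"simulate"`, `"fit"`,
#'   `"posterior"`, `"fixed_points"`, `"modes"`, `"titrate"`; later stages
#'   require earlier ones.
#' @param titrate_probs,titrate_sessions titration settings.
#' @param speed_threshold fixed-point retention threshold.
#' @param verbose print stage progress.
#' @return object of class `run_manifest`: per-stage seeds, settings,
#'   stage outputs (`session`, `model`, `posterior`, `fps`, `basis`,
#'   `titration`) and numeric fingerprints of each output.
#' @export
run_pipeline <- function(kind = "line", seed = 0, n_trials = 120,
                         p_reward = 0.85, n_neurons = 30, config = NULL,
                         stages = c("simulate", "fit", "posterior",
                                    "fixed_points", "modes", "titrate"),
                         titrate_probs = c(0.5, 0.8, 1.0),
                         titrate_sessions = 100,
                         speed_threshold = 3e-4, verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  set.seed(as.integer(seed))
  sub <- sample.int(2^30 - 1, 6)
  names(sub) <- c("system", "simulate", "fit", "posterior",
                  "fixed_points", "titrate")
  say <- function(...) if (verbose) message(sprintf(...))
  fp_num <- function(x) {
    v <- unlist(x, use.names = FALSE)
    v <- v[is.finite(v)]
    c(n = length(v), mean = mean(v), sd = sd(v))
  }
  man <- list(kind = kind, seed = seed, stage_seeds = sub,
              settings = list(n_trials = n_trials, p_reward = p_reward,
                              n_neurons = n_neurons,
                              speed_threshold = speed_threshold),
              fingerprints = list())

  say("simulating %s-attractor session", kind)
  system <- make_system(kind, n_neurons = n_neurons, seed = sub["system"])
  session <- simulate_session(system, n_trials, p_reward,
                              seed = sub["simulate"])
  man$system <- system; man$session <- session
  man$fingerprints$session <- fp_num(session$fluorescence)
  if (!"fit" %in% stages) return(structure(man, class = "run_manifest"))

  if (is.null(config)) config <- lfads_config("small", seed = sub["fit"])
  say("fitting (%d generator units, %d factors)", config$n_generator,
      config$n_factors)
  model <- lfads(session, config)
  man$model <- model
  man$fingerprints$model <- fp_num(model$params)
  if (!any(c("posterior", "fixed_points", "modes", "titrate") %in% stages))
    return(structure(man, class = "run_manifest"))

  say("posterior pass")
  post <- forward_causal(model, session, mode = "mean")
  man$posterior <- post
  man$fingerprints$posterior <- fp_num(post$denoised_means)
  if (!any(c("fixed_points", "modes", "titrate") %in% stages))
    return(structure(man, class = "run_manifest"))

  say("fixed-point search")
  fps <- find_fixed_points(model, post, speed_threshold = speed_threshold,
                           seed = sub["fixed_points"])
  man$fps <- fps
  man$fingerprints$fps <- fp_num(fps$points)
  if ("modes" %in% stages && nrow(fps$points) >= 2L) {
    man$basis <- mode_basis(model, post, session, fps)
    man$fingerprints$basis <- fp_num(man$basis$modes)
  }
  if ("titrate" %in% stages && nrow(fps$points) >= 2L) {
    say("in silico titration")
    lib <- condition_averaged_inputs(post)
    man$titration <- titrate(model, lib, fps, probs = titrate_probs,
                             n_sessions = titrate_sessions,
                             seed = sub["titrate"])
    man$fingerprints$titration <- fp_num(man$titration$curves)
  }
  structure(man, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s attractor, master seed %d\n", x$kind,
              x$seed))
  cat("  stages:", paste(names(x$fingerprints), collapse = ", "), "\n")
  if (!is.null(x$fps))
    cat(sprintf("  attractor classification: %s (%d points)\n",
                x$fps$classification, nrow(x$fps$points)))
  if (!is.null(x$titration))
    cat("  titration slopes:",
        paste(sprintf("%.3g", x$titration$slopes), collapse = ", "), "\n")
  invisible(x)
}
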