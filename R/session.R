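#' Trial-structured population fluorescence container
#'
#' The universal input container for all analysis stages: a
#' trials x time-bins x neurons fluorescence tensor plus per-trial metadata.
#' All trials share the same bin count and cue bin.
#'
#' @param fluorescence numeric array, trials x bins x neurons, no missing
#'   values.
#' @param trial_type character vector of length trials; each entry one of
#'   `"rewarded"`, `"unrewarded"`, `"perturbation"`.
#' @param cue_bin integer, 1-based index of the cue-onset bin within a trial.
#' @param bin_size bin width in seconds (default 0.2, i.e. 200 ms).
#' @param session_id opaque session label.
#' @param neuron_ids optional character labels, one per neuron.
#' @return an object of class `session_data`.
#' @export
session_data <- function(fluorescence, trial_type, cue_bin, bin_size = 0.2,
                         session_id = "session", neuron_ids = NULL) {
  if (!is.array(fluorescence) || length(dim(fluorescence)) != 3L)
    stop("fluorescence must be a trials x bins x neurons array")
  if (anyNA(fluorescence) || !all(is.finite(fluorescence)))
    stop("fluorescence contains missing or non-finite values")
  d <- dim(fluorescence)
  trial_type <- as.character(trial_type)
  if (length(trial_type) != d[1L])
    stop("trial_type must have one entry per trial")
  bad <- setdiff(unique(trial_type),
                 c("rewarded", "unrewarded", "perturbation"))
  if (length(bad))
    stop("unknown trial_type label(s): ", paste(bad, collapse = ", "))
  cue_bin <- as.integer(cue_bin)
  if (length(cue_bin) != 1L || cue_bin < 1L || cue_bin > d[2L])
    stop("cue_bin must be a single bin index within the trial")
  if (!is.numeric(bin_size) || bin_size <= 0)
    stop("bin_size must be positive")
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(d[3L]))
  structure(
    list(fluorescence = fluorescence, trial_type = trial_type,
         cue_bin = cue_bin, bin_size = bin_size,
         session_id = as.character(session_id),
         neuron_ids = as.character(neuron_ids)),
    class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  d <- dim(x$fluorescence)
  cat("<session_data> ", x$session_id, "\n", sep = "")
  cat(sprintf("  %d trials x %d bins x %d neurons (bin %g s, trial %g s)\n",
              d[1], d[2], d[3], x$bin_size, d[2] * x$bin_size))
  tt <- table(x$trial_type)
  cat("  trial types:",
      paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  cat(sprintf("  cue at bin %d (%.1f s)\n", x$cue_bin,
              (x$cue_bin - 1) * x$bin_size))
  invisible(x)
}

#' Number of trials in a session
#' @param data a `session_data` object.
#' @return integer trial count.
#' @export
n_trials <- function(data) dim(data$fluorescence)[1L]

#' Subset a session by trial index
#' @param data a `session_data` object.
#' @param idx integer trial indices (order preserved).
#' @return a `session_data` object with the selected trials.
#' @export
subset_trials <- function(data, idx) {
  out <- data
  out$fluorescence <- data$fluorescence[idx, , , drop = FALSE]
  out$trial_type <- data$trial_type[idx]
  lat <- attr(data, "latents")
  if (!is.null(lat)) attr(out, "latents") <- lat[idx, , , drop = FALSE]
  out
}

#' Write a session to a plain-text JSON container
#'
#' Layout: a single JSON object with fields `fluorescence` (row-major nested
#' array, trials x bins x neurons), `trial_type`, `cue_bin`, `bin_size`,
#' `session_id`, `neuron_ids` and `dim`.  Numbers are written at full
#' precision so a write/read round trip reproduces the tensor bitwise.
#'
#' @param data a `session_data` object.
#' @param path output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_session <- function(data, path) {
  stopifnot(inherits(data, "session_data"))
  obj <- list(
    format = "calfads-session-v1",
    dim = dim(data$fluorescence),
    fluorescence = as.numeric(data$fluorescence),
    trial_type = data$trial_type,
    cue_bin = data$cue_bin,
    bin_size = data$bin_size,
    session_id = data$session_id,
    neuron_ids = data$neuron_ids)
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path file path.
#' @return a `session_data` object.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE)),
                  error = function(e) stop("cannot parse session file ",
                                           path, ": ", conditionMessage(e)))
  req <- c("dim", "fluorescence", "trial_type", "cue_bin", "bin_size",
           "session_id")
  miss <- setdiff(req, names(obj))
  if (length(miss))
    stop("session file is missing field(s): ", paste(miss, collapse = ", "))
  fl <- array(as.numeric(obj$fluorescence), dim = obj$dim)
  session_data(fl, obj$trial_type, obj$cue_bin, obj$bin_size,
               obj$session_id, obj$neuron_ids)
}
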