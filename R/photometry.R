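# Fiber-photometry preprocessing: isosbestic (405 nm) control-channel
# correction, rig-baseline dF/F, and whole-session z-scoring.

#' Dual-channel photometry record
#'
#' @param signal_490 calcium-dependent (490 nm) detector trace.
#' @param control_405 isosbestic (405 nm) control trace, same length.
#' @param fs sampling rate in Hz (default 1017).
#' @param trial_event_times optional event times in seconds.
#' @param rig_baseline_F rig fluorescence measured without the animal
#'   (detector units, >= 0).
#' @return object of class `photometry_record`.
#' @export
photometry_record <- function(signal_490, control_405, fs = 1017,
                              trial_event_times = NULL,
                              rig_baseline_F = 0) {
  if (length(signal_490) != length(control_405))
    stop("signal and control channels must have equal length")
  if (fs <= 0) stop("fs must be positive")
  if (rig_baseline_F < 0) stop("rig_baseline_F must be nonnegative")
  structure(list(signal_490 = as.numeric(signal_490),
                 control_405 = as.numeric(control_405), fs = fs,
                 trial_event_times = trial_event_times,
                 rig_baseline_F = rig_baseline_F),
            class = "photometry_record")
}

#' Isosbestic control-channel correction
#'
#' The 405 nm control channel is resampled to an intermediate 60 Hz grid
#' (linear interpolation), low-pass filtered (zero-phase 2nd-order
#' Butterworth, 2 Hz cutoff), resampled back to the original rate, fit to
#' the 490 nm signal by least squares (affine: gain + offset), and the
#' fitted control is subtracted from the signal.  The affine fit makes the
#' correction invariant to rescaling of the control channel.
#'
#' @param record a [photometry_record()] with at least 2 s of data.
#' @param intermediate_fs intermediate rate in Hz (default 60).
#' @param cutoff_hz low-pass cutoff in Hz (default 2).
#' @return numeric `dF` series, same length as the input.
#' @export
control_correct <- function(record, intermediate_fs = 60, cutoff_hz = 2) {
  stopifnot(inherits(record, "photometry_record"))
  n <- length(record$signal_490)
  if (n / record$fs < 2) stop("need at least 2 s of data")
  t_full <- (seq_len(n) - 1) / record$fs
  t_mid <- seq(0, t_full[n], by = 1 / intermediate_fs)
  c_mid <- approx(t_full, record$control_405, t_mid, rule = 2)$y
  bf <- signal::butter(2, cutoff_hz / (intermediate_fs / 2))
  # odd-reflection padding suppresses zero-state edge transients of the
  # forward-backward filter
  m <- length(c_mid)
  pad <- min(m - 1L, ceiling(3 * intermediate_fs / cutoff_hz))
  padded <- c(2 * c_mid[1L] - rev(c_mid[2L:(pad + 1L)]), c_mid,
              2 * c_mid[m] - rev(c_mid[(m - pad):(m - 1L)]))
  mu <- mean(padded)   # center so internal zero-padding adds no step
  smoothed <- as.numeric(signal::filtfilt(bf, padded - mu)) + mu
  c_smooth <- smoothed[(pad + 1L):(pad + m)]
  c_up <- approx(t_mid, c_smooth, t_full, rule = 2)$y
  fit <- lm(record$signal_490 ~ c_up)
  record$signal_490 - as.numeric(fitted(fit))
}

#' Percent dF/F
#'
#' `100 * dF / (session_mean_F - rig_baseline_F)`: the denominator is the
#' session-mean raw fluorescence with the rig baseline (measured without
#' the animal) subtracted.
#'
#' @param dF corrected fluorescence series (from [control_correct()]).
#' @param rig_baseline_F rig baseline, detector units.
#' @param session_mean_F session-mean raw fluorescence; must exceed the
#'   rig baseline.
#' @return percent dF/F series.
#' @export
dff <- function(dF, rig_baseline_F, session_mean_F) {
  denom <- session_mean_F - rig_baseline_F
  if (!is.finite(denom) || denom <= 0)
    stop("session_mean_F must exceed rig_baseline_F")
  100 * dF / denom
}

#' Whole-session z-scoring
#'
#' Mean and SD are computed on the window from the first trial start to
#' 10 s after the last trial end, then applied to the entire series.
#'
#' @param series numeric trace.
#' @param fs sampling rate in Hz.
#' @param first_trial_start,last_trial_end window anchors in seconds.
#' @return z-scored series (full length).
#' @export
zscore_session <- function(series, fs, first_trial_start,
                           last_trial_end) {
  n <- length(series)
  t <- (seq_len(n) - 1) / fs
  idx <- which(t >= first_trial_start & t <= last_trial_end + 10)
  if (!length(idx)) stop("z-scoring window lies outside the recording")
  m <- mean(series[idx]); s <- sd(series[idx])
  if (!is.finite(s) || s == 0) stop("zero variance in the z-scoring window")
  (series - m) / s
}
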