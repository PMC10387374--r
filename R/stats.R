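# Session-level statistics: task-modulation testing, post-perturbation
# recovery time, ramping classification, hierarchical bootstrap and the
# evidence-integration statistic.

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's convention).  For n <= 25 the
#' exact null distribution of the positive-rank sum V is computed by
#' dynamic-programming convolution over the (tie-averaged) ranks; above
#' that a normal approximation with tie correction and continuity
#' correction is used.  Two-sided p doubles the smaller tail (capped at
#' 1).
#'
#' @param paired_a,paired_b numeric vectors of equal length; at least 5
#'   nonzero differences are required.
#' @param alternative `"two.sided"`, `"greater"` (a > b) or `"less"`.
#' @return list with `statistic` (V), `p.value`, `n` (nonzero pairs) and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  if (n < 5L) stop("need at least 5 nonzero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    # exact: distribution of sum of a random subset of the doubled ranks
    w <- as.integer(round(2 * r))
    tot <- sum(w)
    dp <- numeric(tot + 1L); dp[1L] <- 1
    for (wi in w) {
      shifted <- c(numeric(wi), dp[seq_len(tot + 1L - wi)])
      dp <- dp + shifted
    }
    dp <- dp / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(dp[seq_len(v2 + 1L)])
    p_ge <- sum(dp[(v2 + 1L):(tot + 1L)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sig <- sqrt(sig2)
    cc <- 0.5
    p <- switch(alternative,
                two.sided = {
                  z <- (V - mu - sign(V - mu) * cc) / sig
                  min(1, 2 * pnorm(-abs(z)))
                },
                greater = pnorm((V - mu - cc) / sig, lower.tail = FALSE),
                less = pnorm((V - mu + cc) / sig))
    method <- "normal"
  }
  list(statistic = V, p.value = p, n = n, method = method)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control; adjusted p-values are made
#' monotone by the cumulative minimum from the largest rank (the standard
#' `p.adjust` BH definition).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level for the rejection mask (default 0.05).
#' @return list with `adjusted` p-values and logical `reject` mask
#'   (`adjusted <= alpha`).
#' @export
benjamini_hochberg <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= alpha)
}

window_bins <- function(start_s, len_s, bin_size, origin_bin) {
  # bins covering [start_s, start_s + len_s) relative to origin_bin onset
  first <- origin_bin + round(start_s / bin_size)
  first:(first + round(len_s / bin_size) - 1L)
}

#' Task-modulated neuron detection
#'
#' Compares, per neuron, the average rate in a 1 s pre-cue baseline
#' against four sequential 1 s windows from cue onset (paired two-sided
#' Wilcoxon signed-rank across trials).  A neuron is flagged as
#' task-modulated if any window is significant after Benjamini-Hochberg
#' correction across all neurons x windows at `alpha` (default 0.01).
#'
#' @param rates trials x bins x neurons array for one trial type.
#' @param cue_bin 1-based cue-onset bin.
#' @param bin_size bin width in seconds.
#' @param alpha FDR level (default 0.01).
#' @return list with `modulated` (logical per neuron), `p` and `p_adjusted`
#'   (neurons x 4 matrices).
#' @export
task_modulated <- function(rates, cue_bin, bin_size, alpha = 0.01) {
  stopifnot(length(dim(rates)) == 3L)
  n_tr <- dim(rates)[1L]; n_bins <- dim(rates)[2L]; N <- dim(rates)[3L]
  if (n_tr < 5L) stop("need at least 5 trials")
  base_idx <- window_bins(-1, 1, bin_size, cue_bin)
  win_idx <- lapply(0:3, function(k) window_bins(k, 1, bin_size, cue_bin))
  if (min(base_idx) < 1L || max(win_idx[[4L]]) > n_bins)
    stop("baseline or test windows do not fit within the trial")
  pmat <- matrix(NA_real_, N, 4L)
  for (j in seq_len(N)) {
    base <- rowMeans(rates[, base_idx, j, drop = FALSE])
    for (w in 1:4) {
      tw <- rowMeans(rates[, win_idx[[w]], j, drop = FALSE])
      pmat[j, w] <- if (all(tw == base)) 1 else
        wilcoxon_signed_rank(tw, base)$p.value
    }
  }
  bh <- benjamini_hochberg(as.numeric(pmat), alpha)
  padj <- matrix(bh$adjusted, N, 4L)
  list(modulated = apply(padj <= alpha, 1L, any), p = pmat,
       p_adjusted = padj)
}

#' Post-perturbation recovery time
#'
#' Per neuron: the average rate in a 2 s pre-onset baseline is compared
#' (paired two-sided Wilcoxon) against sequential 0.5 s windows from
#' onset; p-values are BH-corrected across all neurons x windows at
#' `alpha` (default 0.01).  The recovery time is the earliest window start
#' such that that window and the next two are all non-significant; `NA`
#' flags neurons that never recover.
#'
#' @param rates trials x bins x neurons array.
#' @param onset_bin 1-based perturbation-onset bin.
#' @param bin_size bin width in seconds.
#' @param alpha FDR level (default 0.01).
#' @return list with `recovery_s` (per-neuron seconds, `NA` = not
#'   recovered), `p_adjusted` (neurons x windows) and `window_starts_s`.
#' @export
recovery_time <- function(rates, onset_bin, bin_size, alpha = 0.01) {
  stopifnot(length(dim(rates)) == 3L)
  n_bins <- dim(rates)[2L]; N <- dim(rates)[3L]
  wb <- round(0.5 / bin_size)
  if (wb < 1L) stop("bins too coarse for 0.5 s windows")
  n_win <- (n_bins - onset_bin + 1L) %/% wb
  if (n_win < 3L) stop("need at least 3 post-onset 0.5 s windows")
  base_idx <- window_bins(-2, 2, bin_size, onset_bin)
  if (min(base_idx) < 1L) stop("2 s baseline does not fit before onset")
  pmat <- matrix(NA_real_, N, n_win)
  for (j in seq_len(N)) {
    base <- rowMeans(rates[, base_idx, j, drop = FALSE])
    for (w in seq_len(n_win)) {
      idx <- onset_bin + (w - 1L) * wb + seq_len(wb) - 1L
      tw <- rowMeans(rates[, idx, j, drop = FALSE])
      pmat[j, w] <- if (all(tw == base)) 1 else
        wilcoxon_signed_rank(tw, base)$p.value
    }
  }
  padj <- matrix(benjamini_hochberg(as.numeric(pmat), alpha)$adjusted,
                 N, n_win)
  sig <- padj <= alpha
  rec <- rep(NA_real_, N)
  for (j in seq_len(N)) {
    for (w in seq_len(n_win - 2L)) {
      if (!any(sig[j, w:(w + 2L)])) { rec[j] <- (w - 1L) * 0.5; break }
    }
  }
  list(recovery_s = rec, p_adjusted = padj,
       window_starts_s = (seq_len(n_win) - 1L) * 0.5)
}

#' Across-trial ramping classification
#'
#' Ordinary least-squares regression of the per-trial baseline rate on the
#' trial index; the two-sided p-value for a zero slope comes from the
#' t-based confidence interval of the slope.  Significant positive slopes
#' are `"up"`, negative `"down"`, otherwise `"none"`.
#'
#' @param baseline_rates_by_trial numeric vector (>= 10 trials) of
#'   per-trial 2 s pre-cue baseline rates, in session order.
#' @param alpha significance threshold (default 0.05).
#' @return list with `class`, `slope`, `p.value`.
#' @export
classify_ramping <- function(baseline_rates_by_trial, alpha = 0.05) {
  y <- as.numeric(baseline_rates_by_trial)
  n <- length(y)
  if (n < 10L) stop("need at least 10 trials")
  x <- seq_len(n)
  if (var(x) == 0) stop("trial index is constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  slope <- sm["x", "Estimate"]
  p <- if (nrow(sm) < 2L || is.na(sm["x", "Pr(>|t|)"])) 1
       else sm["x", "Pr(>|t|)"]
  cls <- if (p < alpha && slope > 0) "up"
         else if (p < alpha && slope < 0) "down" else "none"
  list(class = cls, slope = slope, p.value = p)
}

as_nested_rates <- function(data) {
  # canonical nesting: sessions -> neurons -> per-trial numeric values
  if (is.numeric(data)) return(list(list(as.numeric(data))))
  if (is.list(data) && all(vapply(data, is.numeric, TRUE)))
    return(list(data))
  if (is.list(data) && all(vapply(data, is.list, TRUE))) return(data)
  stop("data must be a numeric vector, a list of per-neuron vectors, or ",
       "a list of sessions each holding per-neuron vectors")
}

#' Hierarchical (session -> neuron -> trial) bootstrap
#'
#' Each resampled dataset is built by sampling sessions with replacement
#' (matching the session count), then for each drawn session its neurons
#' with replacement (matching that session's neuron count), then for each
#' drawn neuron its trials with replacement (matching that neuron's trial
#' count).  The statistic is evaluated on the pooled resampled values.
#' Mean and SEM are the mean and SD of the resampled statistics; the
#' one-sided p-value is the fraction of resampled statistics on the
#' opposite side of zero from the observed statistic (exact zeros count
#' one half), with add-one smoothing `(k + 1) / (B + 1)` so p is never
#' exactly 0.
#'
#' @param data nested list `sessions -> neurons -> numeric trial values`;
#'   a bare numeric vector or a list of per-neuron vectors is promoted.
#' @param statistic function of a numeric vector (default `mean`).
#' @param n_iter bootstrap iterations (default 100).
#' @param seed RNG seed.
#' @return object of class `bootstrap_result`: `resampled_means`,
#'   `observed`, `mean`, `sem`, `p_one_sided`.
#' @export
hierarchical_bootstrap <- function(data, statistic = mean, n_iter = 100,
                                   seed = 0) {
  nested <- as_nested_rates(data)
  if (!length(nested) || !length(nested[[1L]]) ||
      !length(nested[[1L]][[1L]]))
    stop("empty nesting: need at least 1 session, 1 neuron, 1 trial")
  set.seed(as.integer(seed))
  n_s <- length(nested)
  observed <- statistic(unlist(nested, use.names = FALSE))
  res <- numeric(n_iter)
  for (b in seq_len(n_iter)) {
    vals <- list(); vi <- 0L
    for (s in sample.int(n_s, n_s, replace = TRUE)) {
      sess <- nested[[s]]
      for (j in sample.int(length(sess), length(sess), replace = TRUE)) {
        tr <- sess[[j]]
        vi <- vi + 1L
        vals[[vi]] <- tr[sample.int(length(tr), length(tr),
                                    replace = TRUE)]
      }
    }
    res[b] <- statistic(unlist(vals, use.names = FALSE))
  }
  k <- (if (observed >= 0) sum(res < 0) else sum(res > 0)) +
    0.5 * sum(res == 0)
  structure(
    list(resampled_means = res, observed = observed, mean = mean(res),
         sem = sd(res), p_one_sided = (k + 1) / (n_iter + 1)),
    class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> mean %.4g, sem %.4g, one-sided p = %.3g (B = %d)\n",
    x$mean, x$sem, x$p_one_sided, length(x$resampled_means)))
  invisible(x)
}

#' Evidence-integration statistic
#'
#' Per trial, the 2 s pre-onset baseline mean is subtracted, and the
#' baseline-subtracted mean over the final window (5-7 s from onset) is
#' the per-trial integration value.  Those values are combined across the
#' session -> neuron -> trial hierarchy with [hierarchical_bootstrap()] of
#' the mean; the one-sided p tests whether the integrated change differs
#' from zero in the direction of the observed statistic (significance at
#' 0.05).
#'
#' @param trial_rates a trials x bins matrix (single neuron), a list of
#'   such matrices (neurons of one session), or a list of sessions each a
#'   list of matrices.
#' @param bin_size bin width in seconds.
#' @param onset_bin 1-based cue/perturbation onset bin.
#' @param baseline_s baseline length in seconds before onset (default 2).
#' @param final_window_s final-window start/end in seconds from onset
#'   (default `c(5, 7)`).
#' @param n_iter bootstrap iterations (default 100).
#' @param seed RNG seed.
#' @return a `bootstrap_result` (see [hierarchical_bootstrap()]).
#' @export
integration_statistic <- function(trial_rates, bin_size, onset_bin,
                                  baseline_s = 2,
                                  final_window_s = c(5, 7), n_iter = 100,
                                  seed = 0) {
  if (is.matrix(trial_rates)) trial_rates <- list(list(trial_rates))
  else if (is.list(trial_rates) && all(vapply(trial_rates, is.matrix, TRUE)))
    trial_rates <- list(trial_rates)
  per_trial <- function(M) {
    nb <- ncol(M)
    if ((nb - onset_bin + 1L) * bin_size < final_window_s[2L])
      stop("trials must extend at least ", final_window_s[2L],
           " s past onset")
    bi <- window_bins(-baseline_s, baseline_s, bin_size, onset_bin)
    if (min(bi) < 1L) stop("baseline window does not fit before onset")
    fi <- window_bins(final_window_s[1L],
                      diff(final_window_s), bin_size, onset_bin)
    rowMeans(M[, fi, drop = FALSE]) - rowMeans(M[, bi, drop = FALSE])
  }
  nested <- lapply(trial_rates, function(sess) lapply(sess, per_trial))
  hierarchical_bootstrap(nested, statistic = mean, n_iter = n_iter,
                         seed = seed)
}
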