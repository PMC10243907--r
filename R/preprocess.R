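#' Trim unstable edges from a recording
#'
#' Removes the first and last `trim_s` seconds from every channel (the
#' period when the acquisition system is settling).  Layout timestamps
#' must be re-referenced separately with [shift_layout()] by
#' `-trim_s`.
#'
#' @param rec an [recording()].
#' @param trim_s seconds to drop at each edge (default 30).
#' @return trimmed `ins_recording`.
#' @export
trim_edges <- function(rec, trim_s = 30) {
  stopifnot(inherits(rec, "ins_recording"))
  if (trim_s < 0) stopf("trim_s must be >= 0")
  if (trim_s == 0) return(rec)
  if (duration_s(rec) <= 2 * trim_s) {
    stopf("recording of %.1f s too short to trim %g s at each edge",
          duration_s(rec), trim_s)
  }
  k <- round(trim_s * rec$sampling_rate)
  keep <- seq.int(k + 1L, n_samples(rec) - k)
  out <- rec
  out$data <- rec$data[, keep, drop = FALSE]
  out
}

#' Remove the linear trend from each channel
#'
#' Ordinary least-squares detrending: per channel the best-fitting line
#' (intercept + slope) is subtracted, leaving zero mean and zero OLS
#' slope.  Idempotent.
#'
#' @param x an [recording()], numeric matrix (channels x samples), or
#'   numeric vector.
#' @return same type as the input.
#' @export
detrend <- function(x) UseMethod("detrend")

#' @export
detrend.numeric <- function(x) {
  n <- length(x)
  if (n < 3L) stopf("need >= 3 samples to detrend")
  tt <- seq_len(n) - (n + 1) / 2          # centred time axis
  x - mean(x) - tt * (sum(tt * x) / sum(tt^2))
}

#' @export
detrend.matrix <- function(x) {
  t(apply(x, 1, detrend.numeric))
}

#' @export
detrend.ins_recording <- function(x) {
  out <- x
  out$data <- detrend.matrix(x$data)
  rownames(out$data) <- x$channel_labels
  out
}

#' TDDR parameters
#'
#' Constants of the temporal derivative distribution repair procedure.
#' `tuning_constant` is Tukey's biweight `c` (4.685 gives 95% efficiency
#' under Gaussian noise), `mad_scale` the MAD-to-SD consistency factor
#' 1.4826, `split_freq_hz` the zero-phase low-pass cutoff separating the
#' slow hemodynamic content from the fast fluctuation component that is
#' repaired, and `component` which side of the split the robust
#' reweighting is applied to (`"fluctuation"`, the default, targets
#' sharp spike artifacts; `"low"` is the orientation that targets slow
#' baseline drift).
#'
#' @param tuning_constant Tukey biweight c (> 0).
#' @param mad_scale MAD consistency factor.
#' @param convergence_tol stop when the largest weight change falls
#'   below this.
#' @param max_iterations iteration cap for the robust loop.
#' @param split_freq_hz low-pass cutoff in Hz.
#' @param component `"fluctuation"` or `"low"`.
#' @param gross_trim run a second pass that hard-rejects gross outliers
#'   (`|u| >= 1` at the same `c * MAD` standard) in the *unsplit*
#'   derivative.  A one-sample spike keeps roughly 10% of its amplitude
#'   below a 0.5 Hz cutoff, so a purely banded repair cannot remove it
#'   completely; the trim pass removes that residue while leaving any
#'   sample within the Tukey rejection bound untouched.
#' @return list of class `tddr_params`.
#' @export
tddr_params <- function(tuning_constant = 4.685, mad_scale = 1.4826,
                        convergence_tol = 1e-8, max_iterations = 50,
                        split_freq_hz = 0.5,
                        component = c("fluctuation", "low"),
                        gross_trim = TRUE) {
  if (tuning_constant <= 0) stopf("tuning_constant must be > 0")
  if (convergence_tol <= 0) stopf("convergence_tol must be > 0")
  structure(list(tuning_constant = tuning_constant, mad_scale = mad_scale,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 split_freq_hz = split_freq_hz,
                 component = match.arg(component),
                 gross_trim = isTRUE(gross_trim)),
            class = "tddr_params")
}

#' Motion-artifact correction by temporal derivative distribution repair
#'
#' Robustly reweights the first differences of each channel so that
#' motion artifacts (spikes, abrupt shifts) are suppressed while the
#' hemodynamic signal passes through.  Per channel: the linear trend is
#' removed (and restored at the end); the detrended signal is split at
#' `split_freq_hz` by a zero-phase Butterworth low-pass into a slow part
#' and a fluctuation part; the first differences of the repaired
#' component are iteratively reweighted with Tukey's biweight (weighted
#' mean, MAD scale); the reweighted differences are cumulated back and
#' recombined with the untouched component and the trend.
#'
#' A channel whose derivative has zero robust scale (constant
#' derivative, e.g. a ramp) is returned unchanged: with nothing to
#' down-weight the repair is the identity.  Non-convergence within
#' `max_iterations` proceeds with the last weights and warns.
#'
#' @param rec an [recording()].
#' @param params [tddr_params()].
#' @return repaired `ins_recording`; attribute `"tddr_weights"` holds the
#'   per-channel mean derivative weight (1 = untouched).
#' @export
tddr <- function(rec, params = tddr_params()) {
  stopifnot(inherits(rec, "ins_recording"))
  out <- rec
  wsum <- numeric(n_channels(rec))
  for (i in seq_len(n_channels(rec))) {
    res <- tddr_channel(rec$data[i, ], rec$sampling_rate, params)
    out$data[i, ] <- res$x
    wsum[i] <- res$mean_weight
  }
  attr(out, "tddr_weights") <- setNames(wsum, rec$channel_labels)
  out
}

# Iterated robust location of a derivative series: weighted mean, MAD
# scale, Tukey biweight (or hard-rejection) weights.  Returns NULL when
# the robust scale is zero (constant derivative: nothing to repair).
tddr_robust_weights <- function(d, params, hard = FALSE) {
  w <- rep(1, length(d))
  mu <- 0
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    mu <- sum(w * d) / sum(w)
    r <- d - mu
    sigma <- params$mad_scale * median(abs(r))
    if (sigma == 0) return(NULL)
    u <- r / (params$tuning_constant * sigma)
    w_new <- if (hard) as.numeric(abs(u) < 1) else ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (max(abs(w_new - w)) < params$convergence_tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged) {
    warnf("TDDR did not converge within %d iterations; using last weights",
          params$max_iterations)
  }
  list(w = w, mu = mu)
}

# Reweight the differences of `d_series`, keeping the robust mean in the
# reconstruction so that all-unit weights reproduce the input exactly.
tddr_reintegrate <- function(series, rw) {
  d <- diff(series)
  new_d <- rw$w * (d - rw$mu) + rw$mu
  series[1] + c(0, cumsum(new_d))
}

tddr_channel <- function(x, rate, params) {
  n <- length(x)
  tt <- seq_len(n) - (n + 1) / 2
  slope <- sum(tt * x) / sum(tt^2)
  trend <- mean(x) + tt * slope
  y <- x - trend

  fc <- params$split_freq_hz * 2 / rate
  if (fc < 1) {
    bf <- signal::butter(3, fc)
    low <- signal::filtfilt(bf, y)
  } else {
    low <- y
  }
  fluct <- y - low
  if (identical(params$component, "fluctuation")) {
    rep_part <- fluct; keep_part <- low
  } else {
    rep_part <- low; keep_part <- fluct
  }

  rw <- tddr_robust_weights(diff(rep_part), params)
  mean_w <- 1
  if (is.null(rw)) {
    y2 <- y
  } else {
    y2 <- tddr_reintegrate(rep_part, rw) + keep_part
    mean_w <- mean(rw$w)
  }

  if (params$gross_trim) {
    rw2 <- tddr_robust_weights(diff(y2), params, hard = TRUE)
    if (!is.null(rw2)) {
      y2 <- tddr_reintegrate(y2, rw2)
      mean_w <- min(mean_w, mean(rw2$w))
    }
  }
  list(x = y2 + trend, mean_weight = mean_w)
}
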