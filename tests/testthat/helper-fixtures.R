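# Shared fixtures and independent oracles for the test-suite.

# Small scale grid used wherever the full 106-scale default is overkill.
test_grid <- function() make_scale_grid(2, 80, 48)

# A one-channel recording holding the given signal at 10 Hz.
signal_rec <- function(x, rate = 10, role = "A") {
  recording(matrix(x, nrow = 1), sampling_rate = rate, participant_role = role)
}

# Straightforward, loop-based re-implementation of the two-stage
# derivative repair, independent of the package's vectorised code path.
naive_tddr <- function(x, rate, c_tune = 4.685, mad_k = 1.4826, tol = 1e-8,
                       max_iter = 50) {
  n <- length(x)
  tt <- seq_len(n) - (n + 1) / 2
  b <- sum(tt * x) / sum(tt^2)
  trend <- mean(x) + b * tt
  y <- x - trend
  bf <- signal::butter(3, 0.5 * 2 / rate)
  low <- signal::filtfilt(bf, y)
  fl <- y - low

  loop <- function(d, hard) {
    w <- rep(1, length(d)); mu <- 0
    for (i in seq_len(max_iter)) {
      mu <- sum(w * d) / sum(w)
      r <- d - mu
      sg <- mad_k * median(abs(r))
      if (sg == 0) return(NULL)
      u <- r / (c_tune * sg)
      wn <- numeric(length(d))
      for (j in seq_along(d)) {
        wn[j] <- if (abs(u[j]) < 1) { if (hard) 1 else (1 - u[j]^2)^2 } else 0
      }
      if (max(abs(wn - w)) < tol) return(list(w = wn, mu = mu))
      w <- wn
    }
    list(w = w, mu = mu)
  }
  reint <- function(series, rl) {
    d <- diff(series)
    nd <- rl$w * (d - rl$mu) + rl$mu
    out <- numeric(length(series))
    out[1] <- series[1]
    for (i in seq_along(nd)) out[i + 1] <- out[i] + nd[i]
    out
  }
  rl <- loop(diff(fl), hard = FALSE)
  y2 <- if (is.null(rl)) y else reint(fl, rl) + low
  rl2 <- loop(diff(y2), hard = TRUE)
  if (!is.null(rl2)) y2 <- reint(y2, rl2)
  y2 + trend
}

# Direct time-domain convolution with a normalised sampled Gaussian:
# oracle for the per-scale time smoothing.
naive_gauss_smooth <- function(x, sigma) {
  h <- ceiling(6 * sigma)
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (i - h):(i + h)
    ok <- idx >= 1 & idx <= n
    out[i] <- sum(x[idx[ok]] * k[ok]) / sum(k[ok])
  }
  out
}

# Band-limited lagged dyad signals: shared component at f0, C lagging A
# by lag_s, plus independent white noise.
lagged_pair <- function(n, rate, f0, bw, lag_s, noise_sd = 0.1) {
  k <- round(lag_s * rate)
  f <- c(0, seq_len(n + k - 1)) / (n + k) * rate
  f <- pmin(f, rate - f)
  amp <- exp(-0.5 * ((f - f0) / bw)^2); amp[1] <- 0
  m <- Re(fft(fft(rnorm(n + k)) * amp, inverse = TRUE)) / (n + k)
  m <- m / sd(m)
  list(A = m[(k + 1):(k + n)] + noise_sd * rnorm(n),
       C = m[1:n] + noise_sd * rnorm(n))
}

# INS spectra table (dyad, condition, scale_index, period_s, value) of
# pure exchangeable noise, smooth across scales: a null input for the
# band-selection machinery.
null_spectra <- function(n_dyads, conditions, n_scales, periods = NULL,
                         ar = 0.9) {
  if (is.null(periods)) periods <- exp(seq(log(12), log(80), length.out = n_scales))
  rows <- list()
  for (d in seq_len(n_dyads)) {
    for (cond in conditions) {
      e <- as.numeric(arima.sim(list(ar = ar), n_scales))
      rows[[length(rows) + 1L]] <- data.frame(
        dyad = sprintf("d%02d", d), condition = cond,
        scale_index = seq_len(n_scales), period_s = periods, value = e)
    }
  }
  do.call(rbind, rows)
}
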