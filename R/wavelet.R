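#' Morlet wavelet parameters
#'
#' The analysis wavelet is the complex Morlet with dimensionless centre
#' frequency `omega0` (default 6, the usual choice that balances time and
#' frequency resolution and makes the wavelet numerically admissible).
#' The Fourier factor converting scale to Fourier period is
#' `4 * pi / (omega0 + sqrt(2 + omega0^2))`, about 1.033 for `omega0 = 6`.
#'
#' @param omega0 dimensionless centre frequency, must be >= 5.
#' @return list of class `morlet_params`.
#' @export
morlet_params <- function(omega0 = 6) {
  if (!is_scalar_num(omega0) || omega0 < 5) {
    stopf("omega0 must be >= 5 for practical admissibility")
  }
  structure(list(omega0 = omega0,
                 fourier_factor = 4 * pi / (omega0 + sqrt(2 + omega0^2))),
            class = "morlet_params")
}

#' Geometric grid of wavelet scales
#'
#' Builds the scale grid used throughout the coherence analysis:
#' `n_scales` scales spaced geometrically between `min_scale` and
#' `max_scale` seconds (defaults 0.3 s, 128 s, 106 scales).  Each scale's
#' Fourier period is `scale * fourier_factor(omega0)` and its frequency is
#' the reciprocal period.
#'
#' @param min_scale,max_scale scale range in seconds, `0 < min < max`.
#' @param n_scales number of scales (>= 2).
#' @param params [morlet_params()].
#' @return list of class `scale_grid` with elements `scales`, `periods`
#'   (seconds), `freqs` (Hz), and the spacing in decades per step.
#' @examples
#' g <- make_scale_grid(0.3, 128, 106)
#' range(g$periods)
#' @export
make_scale_grid <- function(min_scale = 0.3, max_scale = 128, n_scales = 106,
                            params = morlet_params()) {
  if (!is_scalar_num(min_scale) || !is_scalar_num(max_scale) ||
      min_scale <= 0 || max_scale <= min_scale) {
    stopf("need 0 < min_scale < max_scale")
  }
  if (n_scales < 2) stopf("n_scales must be >= 2")
  k <- seq_len(n_scales) - 1L
  scales <- min_scale * (max_scale / min_scale)^(k / (n_scales - 1))
  periods <- scales * params$fourier_factor
  structure(list(scales = scales,
                 periods = periods,
                 freqs = 1 / periods,
                 n_scales = as.integer(n_scales),
                 step_decades = log10(max_scale / min_scale) / (n_scales - 1),
                 params = params),
            class = "scale_grid")
}

#' @rdname make_scale_grid
#' @param x a `scale_grid`.
#' @param ... ignored.
#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf("<scale_grid> %d scales, %.3g-%.4g s (periods %.3g-%.4g s)\n",
              x$n_scales, min(x$scales), max(x$scales),
              min(x$periods), max(x$periods)))
  invisible(x)
}

#' Continuous wavelet transform with the Morlet wavelet
#'
#' FFT-based CWT: the signal is zero-padded to the next power of two
#' that also leaves room for the largest wavelet's support (three times
#' the maximum scale), multiplied in the frequency domain by scaled,
#' energy-normalised Morlet daughters, and transformed back.  Padding
#' strictly beyond the wavelet support matters: with fewer zeros the
#' FFT convolution is effectively circular at the largest scales, the
#' two ends of the record contaminate each other, and quantities
#' compared across different record lengths (e.g. a lag scan) pick up
#' jumps wherever the padded length changes.  The transform is linear
#' in the input.
#'
#' @param x numeric signal (finite, length >= 2).
#' @param rate sampling rate in Hz.
#' @param grid [make_scale_grid()].
#' @param params [morlet_params()].
#' @return complex matrix, scales x time.
#' @export
cwt_morlet <- function(x, rate, grid = make_scale_grid(),
                       params = grid$params) {
  if (anyNA(x) || !all(is.finite(x))) stopf("signal contains non-finite samples")
  n <- length(x)
  if (n < 2L) stopf("signal must have >= 2 samples")
  dt <- 1 / rate
  N <- next_pow2(n + ceiling(3 * max(grid$scales) * rate))
  k <- 0:(N - 1)
  omega <- 2 * pi * ifelse(k <= N / 2, k, k - N) / (N * dt)
  pos <- omega > 0
  X <- fft(c(x, rep(0, N - n)))
  ns <- grid$n_scales
  daughters <- matrix(0, N, ns)
  for (j in seq_len(ns)) {
    s <- grid$scales[j]
    d <- numeric(N)
    d[pos] <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-0.5 * (s * omega[pos] - params$omega0)^2)
    daughters[, j] <- d
  }
  W <- mvfft(daughters * X, inverse = TRUE) / N
  t(W[seq_len(n), , drop = FALSE])
}

# Cone of influence: maximum trustworthy Fourier period at each time point,
# from the sqrt(2)*s e-folding time of the Morlet envelope.
coi_periods <- function(n, rate, params = morlet_params()) {
  d <- pmin(seq_len(n) - 1L, n - seq_len(n)) / rate
  params$fourier_factor * d / sqrt(2)
}

# Memo cache for smoothing operators: lag scans rebuild identical
# kernels for every dyad at the same overlap length, so entries are
# keyed by (grid, rate, nt, width) and the cache is reset when it grows
# past ~300 MB.
.ops_cache <- new.env(parent = emptyenv())

# Precompute the smoothing operator for fields on (grid, rate, nt):
# per-scale Gaussian time kernels in the frequency domain, the edge
# renormalisation mask (smoothing of the all-ones field), and the half
# width of the boxcar across scales.
smooth_ops <- function(grid, rate, nt, scale_width_oct = 0.6) {
  key <- paste(rate, nt, scale_width_oct, grid$n_scales,
               grid$scales[1], grid$scales[grid$n_scales],
               grid$params$omega0, sep = "|")
  hit <- get0(key, .ops_cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  ops <- smooth_ops_build(grid, rate, nt, scale_width_oct)
  bytes <- get0("bytes", .ops_cache, ifnotfound = 0) +
    as.numeric(object.size(ops))
  if (bytes > 3e8) {
    rm(list = ls(.ops_cache), envir = .ops_cache)
    bytes <- as.numeric(object.size(ops))
  }
  assign("bytes", bytes, .ops_cache)
  .ops_cache[[key]] <- ops
  ops
}

smooth_ops_build <- function(grid, rate, nt, scale_width_oct = 0.6) {
  # Gaussian time window with SD = scale seconds, the cited toolbox's
  # smoothing convention
  sigma <- grid$scales * rate                    # samples
  N <- next_pow2(nt + ceiling(6 * max(sigma)))
  k <- 0:(N - 1)
  om <- 2 * pi * ifelse(k <= N / 2, k, k - N) / N
  ker <- exp(-0.5 * outer(om^2, sigma^2))        # N x n_scales, real
  ones_f <- fft(c(rep(1, nt), rep(0, N - nt)))
  mask <- Re(mvfft(ker * ones_f, inverse = TRUE)) / N
  mask <- t(mask[seq_len(nt), , drop = FALSE])   # n_scales x nt
  # boxcar width is specified in octaves (the cited toolbox convention);
  # convert to grid steps, which are spaced in decades
  list(N = N, nt = nt, ker = ker, mask = mask,
       half_steps = floor(scale_width_oct * log10(2) / 2 /
                          grid$step_decades + 1e-9))
}

smooth_time_op <- function(field, ops) {
  nt <- ops$nt
  P <- rbind(t(field), matrix(0, ops$N - nt, nrow(field)))
  S <- mvfft(ops$ker * mvfft(P), inverse = TRUE) / ops$N
  out <- t(S[seq_len(nt), , drop = FALSE]) / ops$mask
  if (is.complex(field)) out else Re(out)
}

smooth_scale_op <- function(field, ops) {
  h <- ops$half_steps
  if (h < 1L) return(field)
  ns <- nrow(field)
  cs <- apply(field, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = ns)
  lo <- pmax(seq_len(ns) - h, 1L)
  hi <- pmin(seq_len(ns) + h, ns)
  upper <- cs[hi, , drop = FALSE]
  lower <- rbind(if (is.complex(field)) complex(real = rep(0, ncol(field)))
                 else rep(0, ncol(field)),
                 cs)[lo, , drop = FALSE]
  (upper - lower) / (hi - lo + 1L)
}

#' Smooth a scale-by-time field
#'
#' The smoothing that turns raw cross-wavelet products into a consistent
#' coherence estimate: per-scale Gaussian smoothing in time with standard
#' deviation equal to the scale in seconds, followed by a boxcar across scales
#' of total width `scale_width_oct` octaves (default 0.6, the convention
#' of the standard wavelet-coherence toolbox).  A much wider scale window
#' is not harmless: when one signal lags the other, the cross-wavelet
#' phase winds across frequency, and averaging it over a wide scale span
#' cancels genuine coherence.  Both kernels are normalised (edges
#' renormalised against the smoothed indicator), so a constant field
#' passes through unchanged.
#'
#' @param field numeric or complex matrix, scales x time.
#' @param grid [make_scale_grid()] matching `nrow(field)`.
#' @param rate sampling rate in Hz.
#' @param scale_width_oct boxcar width across scales, in octaves.
#' @return smoothed matrix of the same shape.
#' @export
smooth_field <- function(field, grid, rate, scale_width_oct = 0.6) {
  if (nrow(field) != grid$n_scales) {
    stopf("field has %d rows but grid %d scales", nrow(field), grid$n_scales)
  }
  ops <- smooth_ops(grid, rate, ncol(field), scale_width_oct)
  smooth_scale_op(smooth_time_op(field, ops), ops)
}

# Per-signal precomputation shared by all pairs involving that signal:
# scale-normalised transform Wn = W / sqrt(s) and smoothed power S(|Wn|^2).
wtc_precompute <- function(x, rate, grid, params, ops) {
  # remove the mean so an offset cannot leak through the zero padding;
  # makes coherence invariant to per-channel gain and offset
  W <- cwt_morlet(x - mean(x), rate, grid, params)
  Wn <- W / sqrt(grid$scales)   # column-recycled over time: rows are scales
  P <- smooth_scale_op(smooth_time_op(Mod(Wn)^2, ops), ops)
  list(Wn = Wn, P = P)
}

wtc_from_pre <- function(preA, preC, ops) {
  S12 <- smooth_scale_op(smooth_time_op(preA$Wn * Conj(preC$Wn), ops), ops)
  r2 <- Mod(S12)^2 / (preA$P * preC$P)
  r2[r2 < 0] <- 0
  r2[r2 > 1] <- 1
  r2
}

#' Wavelet transform coherence between two signals
#'
#' Computes the squared wavelet coherence
#' \deqn{R^2(s,t) = \frac{|S(W_{xy}/s)|^2}{S(|W_x|^2/s)\, S(|W_y|^2/s)}}
#' where `S` is [smooth_field()].  Values are clipped to `[0, 1]`.  With
#' `smooth = FALSE` the estimate degenerates to 1 everywhere (the
#' classical identity that unsmoothed wavelet coherence is trivial),
#' which the test-suite uses to guard the smoothing step.
#'
#' @param x,y equal-length finite numeric signals.
#' @param rate sampling rate in Hz.
#' @param grid [make_scale_grid()].
#' @param params [morlet_params()].
#' @param smooth logical; disable smoothing only for diagnostics.
#' @param scale_width_oct passed to [smooth_field()].
#' @return object of class `coherence_map`: list with `values`
#'   (scales x time matrix in `[0,1]`), `scale_grid`, `sampling_rate`,
#'   `times` (seconds), and `coi` (maximum valid period per time point).
#' @examples
#' g <- make_scale_grid(1, 16, 12)
#' m <- wtc(rnorm(256), rnorm(256), rate = 10, grid = g)
#' range(m$values)
#' @export
wtc <- function(x, y, rate, grid = make_scale_grid(), params = grid$params,
                smooth = TRUE, scale_width_oct = 0.6) {
  if (length(x) != length(y)) stopf("signals differ in length")
  n <- length(x)
  if (n < 2 * max(grid$scales) * rate) {
    warnf("signal of %d samples is short for max scale %g s: cone of influence dominates",
          n, max(grid$scales))
  }
  if (!smooth) {
    Wx <- cwt_morlet(x - mean(x), rate, grid, params)
    Wy <- cwt_morlet(y - mean(y), rate, grid, params)
    r2 <- Mod(Wx * Conj(Wy))^2 / (Mod(Wx)^2 * Mod(Wy)^2)
    r2[!is.finite(r2)] <- 1
  } else {
    ops <- smooth_ops(grid, rate, n, scale_width_oct)
    preA <- wtc_precompute(x, rate, grid, params, ops)
    preC <- wtc_precompute(y, rate, grid, params, ops)
    r2 <- wtc_from_pre(preA, preC, ops)
  }
  structure(list(values = r2,
                 scale_grid = grid,
                 sampling_rate = rate,
                 times = (seq_len(n) - 1L) / rate,
                 coi = coi_periods(n, rate, params)),
            class = "coherence_map")
}

#' @rdname wtc
#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf("<coherence_map> %d scales x %d samples @ %g Hz, mean R^2 = %.3f\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              mean(x$values)))
  invisible(x)
}

#' Fisher z transform of coherence
#'
#' Variance-stabilising transform applied before averaging coherence:
#' `z = atanh(min(sqrt(R2), 1 - 1e-7))`, i.e. the transform of the
#' coherence magnitude `r = sqrt(R2)` by correlation analogy.  Set
#' `square_root = FALSE` to transform the squared coherence directly.
#'
#' @param value coherence values in `[0, 1]` (vector or matrix).
#' @param square_root take `sqrt` before `atanh` (default TRUE).
#' @param eps guard below 1 so the transform stays finite.
#' @return transformed values, same shape as the input.
#' @examples
#' fisher_z(0.25)  # atanh(0.5)
#' @export
fisher_z <- function(value, square_root = TRUE, eps = 1e-7) {
  v <- value
  if (any(v < -1e-9 | v > 1 + 1e-9)) stopf("coherence values outside [0, 1]")
  v[v < 0] <- 0
  v[v > 1] <- 1
  r <- if (square_root) sqrt(v) else v
  atanh(pmin(r, 1 - eps))
}
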