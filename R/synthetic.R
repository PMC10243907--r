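#' Specification of an injected inter-brain coupling
#'
#' Describes one band-limited, time-lagged shared component between a
#' channel of participant A and a channel of participant C.  The shared
#' component is a Gaussian process with a Gaussian spectral window
#' (centre `center_freq`, width `bandwidth`), not a sinusoid, so that
#' coherence rather than trivially perfect correlation is the quantity a
#' detector can recover.  `strength` is the fraction of channel variance
#' carried by the shared component; positive `lag_s` means C's copy lags
#' A's by that many seconds.
#'
#' @param chA,chC channel labels on participant A and C.
#' @param center_freq centre frequency in Hz.
#' @param bandwidth spectral standard deviation in Hz.
#' @param lag_s lag in seconds, |lag_s| <= 26; `lag_s * sampling_rate`
#'   must be an integer (lags are whole samples by construction).
#' @param strength variance fraction in `[0, 1]`.
#' @param conditions conditions in which the coupling is active, subset
#'   of `CI`, `SI`, `CC`.
#' @return list of class `coupling_spec`.
#' @export
coupling_spec <- function(chA, chC, center_freq, bandwidth, lag_s, strength,
                          conditions) {
  if (strength < 0 || strength > 1) stopf("strength must be in [0, 1]")
  if (abs(lag_s) > 26) stopf("|lag_s| must be <= 26 s")
  if (bandwidth <= 0 || center_freq <= 0) stopf("need positive center_freq and bandwidth")
  bad <- setdiff(conditions, c("CI", "SI", "CC"))
  if (length(bad)) stopf("couplings cannot be active in: %s", paste(bad, collapse = ", "))
  structure(list(chA = chA, chC = chC, center_freq = center_freq,
                 bandwidth = bandwidth, lag_s = lag_s, strength = strength,
                 conditions = conditions),
            class = "coupling_spec")
}

#' Physiological and instrumental noise model for simulated HbO
#'
#' Each simulated channel is a standardized mixture of a `1/f^a`
#' background, sinusoidal cardiac (~1 Hz), respiratory (~0.3 Hz) and
#' Mayer-wave (~0.1 Hz) components with random phases, and white
#' measurement noise.  Amplitudes are standard deviations relative to
#' the unit-variance `1/f` background.
#'
#' @param one_over_f_exponent spectral slope `a` of the background.
#' @param cardiac,respiratory,mayer lists `list(freq_hz=, amplitude=)`.
#' @param white_sd white-noise standard deviation.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(one_over_f_exponent = 1,
                       cardiac = list(freq_hz = 1.0, amplitude = 0.25),
                       respiratory = list(freq_hz = 0.3, amplitude = 0.2),
                       mayer = list(freq_hz = 0.1, amplitude = 0.3),
                       white_sd = 0.2) {
  amps <- c(cardiac$amplitude, respiratory$amplitude, mayer$amplitude, white_sd)
  if (any(amps < 0)) stopf("noise amplitudes must be >= 0")
  structure(list(one_over_f_exponent = one_over_f_exponent, cardiac = cardiac,
                 respiratory = respiratory, mayer = mayer, white_sd = white_sd),
            class = "noise_spec")
}

#' Motion-artifact model
#'
#' Spikes are single-sample excursions; shifts are step changes that
#' persist to the end of the recording.  Rates are Poisson events per
#' minute per channel; amplitudes are drawn `N(0, (amplitude_sd * channel
#' SD)^2)`.
#'
#' @param spike_rate,shift_rate events per minute (>= 0).
#' @param spike_amplitude_sd,shift_amplitude_sd amplitude scale in
#'   multiples of the channel standard deviation.
#' @return list of class `artifact_spec`.
#' @export
artifact_spec <- function(spike_rate = 0.5, spike_amplitude_sd = 6,
                          shift_rate = 0.1, shift_amplitude_sd = 2) {
  if (spike_rate < 0 || shift_rate < 0) stopf("artifact rates must be >= 0")
  structure(list(spike_rate = spike_rate,
                 spike_amplitude_sd = spike_amplitude_sd,
                 shift_rate = shift_rate,
                 shift_amplitude_sd = shift_amplitude_sd),
            class = "artifact_spec")
}

#' Default condition-dependent couplings
#'
#' Two couplings emulating the contrast the analysis is designed to
#' detect on the standard 26-channel montage: a slow (0.025 Hz,
#' periods ~40 s) coupling between A's left TPJ channel (CH15) and C's
#' right TPJ channel (CH24), lagged 17 s and stronger under simultaneous
#' interpretation, and a faster (0.065 Hz) time-aligned coupling between
#' the two interlocutors' left IFG channels (CH17, CH8), stronger under
#' consecutive interpretation.
#'
#' The spectral width of the shared component (0.010 Hz) sets its
#' temporal correlation to roughly 16 s: turn-locked coupling with a
#' few-seconds jitter.  The width balances two failure modes: a much
#' narrower window leaves the lag of a 40 s-period coupling
#' ill-determined (the coherence profile over lags is flat across
#' +/-10 s, so no estimator can place the peak), while a much wider one
#' spreads the coupling so far across frequency that, at a 17 s lag, the
#' winding cross-wavelet phase cancels its unlagged coherence and band
#' selection loses the band.
#'
#' @param strong,weak variance fractions for the favoured/unfavoured
#'   condition.
#' @return list of [coupling_spec()]s.
#' @export
default_couplings <- function(strong = 0.7, weak = 0.1) {
  list(
    coupling_spec("CH15", "CH24", 0.025, 0.010, 17, strong, "SI"),
    coupling_spec("CH15", "CH24", 0.025, 0.010, 17, weak,   "CI"),
    coupling_spec("CH17", "CH8",  0.065, 0.015, 0,  strong, "CI"),
    coupling_spec("CH17", "CH8",  0.065, 0.015, 0,  weak,   "SI")
  )
}

#' Simulation configuration
#'
#' Bundles everything [generate_dyad()] and [generate_cohort()] need.
#' All stochastic output is fully determined by `(seed, config)`.
#'
#' @param n_dyads number of dyads (>= 2 for any group statistics).
#' @param n_channels channels per participant (default 26).
#' @param sampling_rate Hz (default 10).
#' @param duration_s named vector of per-condition durations in seconds;
#'   a scalar applies to all conditions.
#' @param couplings list of [coupling_spec()].
#' @param noise [noise_spec()].
#' @param artifacts [artifact_spec()].
#' @param strength_jitter_sd per-dyad Gaussian jitter (SD) added to each
#'   coupling's nominal strength, shared across that coupling's
#'   conditions: this is the between-dyad variability that behavioural
#'   scores can correlate with.
#' @param seed integer master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_dyads = 10, n_channels = 26, sampling_rate = 10,
                       duration_s = c(CI = 480, SI = 390, CC = 390,
                                      rest = 300, rest_rain = 300),
                       couplings = default_couplings(),
                       noise = noise_spec(),
                       artifacts = artifact_spec(),
                       strength_jitter_sd = 0.1,
                       seed = 1) {
  if (length(duration_s) == 1L && is.null(names(duration_s))) {
    duration_s <- setNames(rep(duration_s, 5),
                           c("CI", "SI", "CC", "rest", "rest_rain"))
  }
  labels <- paste0("CH", seq_len(n_channels))
  for (cp in couplings) {
    stopifnot(inherits(cp, "coupling_spec"))
    if (!cp$chA %in% labels || !cp$chC %in% labels) {
      stopf("coupling %s-%s outside the %d-channel montage",
            cp$chA, cp$chC, n_channels)
    }
    if (cp$center_freq >= sampling_rate / 2) {
      stopf("coupling centre frequency %g Hz at or above Nyquist", cp$center_freq)
    }
    k <- cp$lag_s * sampling_rate
    if (abs(k - round(k)) > 1e-9) {
      stopf("lag %g s is not a whole number of samples at %g Hz",
            cp$lag_s, sampling_rate)
    }
  }
  structure(list(n_dyads = as.integer(n_dyads), n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, duration_s = duration_s,
                 couplings = couplings, noise = noise, artifacts = artifacts,
                 strength_jitter_sd = strength_jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# --- noise primitives (called inside with_seed blocks) -----------------

# 1/f^a background via spectral synthesis, standardized to unit SD.
one_over_f_noise <- function(n, rate, exponent) {
  f <- c(0, seq_len(n - 1)) / n * rate
  f <- pmin(f, rate - f)                       # two-sided |f|
  amp <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(fft(rnorm(n)) * amp, inverse = TRUE)) / n
  x / sd(x)
}

# Band-limited Gaussian process: white noise shaped by a Gaussian
# spectral window centred on f0, standardized to unit SD.
band_limited_noise <- function(n, rate, f0, bw) {
  f <- c(0, seq_len(n - 1)) / n * rate
  f <- pmin(f, rate - f)
  amp <- exp(-0.5 * ((f - f0) / bw)^2)
  amp[1] <- 0
  x <- Re(fft(fft(rnorm(n)) * amp, inverse = TRUE)) / n
  x / sd(x)
}

# One channel of physiological noise, standardized to unit SD.
physio_channel <- function(n, rate, ns) {
  tt <- (seq_len(n) - 1) / rate
  x <- one_over_f_noise(n, rate, ns$one_over_f_exponent)
  for (comp in list(ns$cardiac, ns$respiratory, ns$mayer)) {
    if (comp$amplitude > 0) {
      x <- x + comp$amplitude * sqrt(2) *
        sin(2 * pi * comp$freq_hz * tt + runif(1, 0, 2 * pi))
    }
  }
  if (ns$white_sd > 0) x <- x + ns$white_sd * rnorm(n)
  x / sd(x)
}

coupling_key <- function(cp) {
  paste(cp$chA, cp$chC, cp$center_freq, cp$lag_s, sep = "|")
}

# Per-dyad realized strength: nominal + jitter shared across conditions
# for the same coupling (same pair/frequency/lag), clamped to [0, 1].
realized_strength <- function(config, dyad_id, cp) {
  if (config$strength_jitter_sd <= 0) return(cp$strength)
  j <- with_seed(child_seed(config$seed, "jitter", dyad_id, coupling_key(cp)),
                 rnorm(1, 0, config$strength_jitter_sd))
  min(max(cp$strength + j, 0), 1)
}

#' Generate one dyad's recordings for one condition
#'
#' Every channel is an independent realization of the configured noise
#' model; for each coupling active in `condition`, a band-limited shared
#' component is added to the named channel of A and, delayed by `lag_s`,
#' to the named channel of C, with mixing weights `sqrt(1 - strength)`
#' and `sqrt(strength)` so the shared component carries exactly the
#' configured variance fraction.  Rest conditions (`rest`, `rest_rain`)
#' never receive couplings.  Motion artifacts are injected afterwards at
#' the configured rates.
#'
#' @param config [sim_config()].
#' @param dyad_id dyad identifier (string or integer).
#' @param condition one of `CI`, `SI`, `CC`, `rest`, `rest_rain`.
#' @param keep_components also return the shared component series
#'   (`$shared`), for diagnostics.
#' @return list with recordings `A` and `C`, ground-truth data frame
#'   `truth` (one row per injected coupling: pair, centre frequency,
#'   bandwidth, lag, realized strength), and optionally `shared`.
#' @export
generate_dyad <- function(config, dyad_id, condition, keep_components = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dur <- config$duration_s[[condition]]
  if (is.null(dur)) stopf("no duration configured for condition %s", condition)
  n <- round(dur * config$sampling_rate)
  rate <- config$sampling_rate
  labels <- paste0("CH", seq_len(config$n_channels))
  active <- if (condition %in% c("rest", "rest_rain")) list() else
    Filter(function(cp) condition %in% cp$conditions, config$couplings)
  if (length(active)) {
    if (anyDuplicated(vapply(active, `[[`, "", "chA")) ||
        anyDuplicated(vapply(active, `[[`, "", "chC"))) {
      stopf("more than one active coupling on a single channel in condition %s",
            condition)
    }
  }

  out <- with_seed(child_seed(config$seed, dyad_id, condition), {
    shared <- list()
    for (cp in active) {
      k <- as.integer(round(abs(cp$lag_s) * rate))
      m <- band_limited_noise(n + k, rate, cp$center_freq, cp$bandwidth)
      if (cp$lag_s >= 0) {             # C lags A
        sA <- m[(k + 1):(k + n)]; sC <- m[1:n]
      } else {                         # C leads A
        sA <- m[1:n]; sC <- m[(k + 1):(k + n)]
      }
      shared[[coupling_key(cp)]] <- list(A = sA / sd(sA), C = sC / sd(sC))
    }
    mk <- function(role) {
      dat <- matrix(0, config$n_channels, n, dimnames = list(labels, NULL))
      for (i in seq_len(config$n_channels)) {
        dat[i, ] <- physio_channel(n, rate, config$noise)
      }
      dat
    }
    datA <- mk("A"); datC <- mk("C")
    truth <- list()
    for (cp in active) {
      st <- realized_strength(config, dyad_id, cp)
      sh <- shared[[coupling_key(cp)]]
      datA[cp$chA, ] <- sqrt(1 - st) * datA[cp$chA, ] + sqrt(st) * sh$A
      datC[cp$chC, ] <- sqrt(1 - st) * datC[cp$chC, ] + sqrt(st) * sh$C
      truth[[length(truth) + 1L]] <- data.frame(
        dyad = as.character(dyad_id), condition = condition,
        chA = cp$chA, chC = cp$chC, center_freq = cp$center_freq,
        bandwidth = cp$bandwidth, lag_s = cp$lag_s,
        strength = st, nominal_strength = cp$strength)
    }
    recA <- recording(datA, rate, "A", labels)
    recC <- recording(datC, rate, "C", labels)
    if (!is.null(config$artifacts)) {
      recA <- inject_motion_artifacts(recA, config$artifacts,
                                      child_seed(config$seed, dyad_id, condition, "artA"))
      recC <- inject_motion_artifacts(recC, config$artifacts,
                                      child_seed(config$seed, dyad_id, condition, "artC"))
    }
    list(A = recA, C = recC,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(dyad = character(0), condition = character(0),
                      chA = character(0), chC = character(0),
                      center_freq = numeric(0), bandwidth = numeric(0),
                      lag_s = numeric(0), strength = numeric(0),
                      nominal_strength = numeric(0)),
         shared = if (keep_components) shared else NULL)
  })
  out
}

#' Inject spike and shift motion artifacts
#'
#' Event counts per channel are Poisson with the configured per-minute
#' rates; spike amplitudes and shift amplitudes are Gaussian in units of
#' the channel SD.  Event times, types and amplitudes are recorded in
#' the `"artifact_events"` attribute of the returned recording.
#'
#' @param rec an [recording()].
#' @param spec an [artifact_spec()].
#' @param seed integer seed (required for reproducibility).
#' @return recording with artifacts added.
#' @export
inject_motion_artifacts <- function(rec, spec, seed) {
  stopifnot(inherits(rec, "ins_recording"), inherits(spec, "artifact_spec"))
  minutes <- duration_s(rec) / 60
  n <- n_samples(rec)
  events <- list()
  out <- rec
  with_seed(seed, {
    for (i in seq_len(n_channels(rec))) {
      s <- sd(rec$data[i, ])
      n_spk <- rpois(1, spec$spike_rate * minutes)
      n_shf <- rpois(1, spec$shift_rate * minutes)
      if (n_spk > 0) {
        at <- sample.int(n, n_spk)
        amp <- rnorm(n_spk, 0, spec$spike_amplitude_sd * s)
        out$data[i, at] <- out$data[i, at] + amp
        events[[length(events) + 1L]] <- data.frame(
          channel = rec$channel_labels[i], type = "spike", sample = at,
          amplitude = amp)
      }
      if (n_shf > 0) {
        at <- sample.int(n, n_shf)
        amp <- rnorm(n_shf, 0, spec$shift_amplitude_sd * s)
        for (j in seq_len(n_shf)) {
          out$data[i, at[j]:n] <- out$data[i, at[j]:n] + amp[j]
        }
        events[[length(events) + 1L]] <- data.frame(
          channel = rec$channel_labels[i], type = "shift", sample = at,
          amplitude = amp)
      }
    }
  })
  attr(out, "artifact_events") <- if (length(events)) do.call(rbind, events) else
    data.frame(channel = character(0), type = character(0),
               sample = integer(0), amplitude = numeric(0))
  out
}

#' Generate a full cohort of dyads across conditions
#'
#' Produces `n_dyads` dyads under the requested task conditions plus the
#' matched rest baselines: plain `rest` (baseline for SI and CC) and
#' `rest_rain` (baseline for CI, emulating the rain-sound masking rest).
#' Rest recordings share the noise model but never the couplings.
#'
#' @param config [sim_config()].
#' @param conditions task conditions to simulate (default CI and SI).
#' @return list of class `ins_cohort` with elements `recordings`
#'   (`recordings[[dyad]][[condition]]$A` / `$C`), `layouts` (one
#'   [session_layout()] per condition), `truth` (row-bound ground
#'   truth), and `config`.
#' @export
generate_cohort <- function(config, conditions = c("CI", "SI")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_dyads < 2) stopf("need >= 2 dyads for group statistics")
  rests <- unique(c("rest"[any(conditions %in% c("SI", "CC"))],
                    "rest_rain"[any(conditions == "CI")]))
  all_conds <- c(conditions, rests)
  dyads <- sprintf("dyad%02d", seq_len(config$n_dyads))
  recordings <- list()
  truth <- list()
  for (d in dyads) {
    recordings[[d]] <- list()
    for (cond in all_conds) {
      g <- generate_dyad(config, d, cond)
      recordings[[d]][[cond]] <- list(A = g$A, C = g$C)
      if (nrow(g$truth)) truth[[length(truth) + 1L]] <- g$truth
    }
  }
  layouts <- lapply(setNames(all_conds, all_conds), function(cond) {
    condition_layout(cond, config$duration_s[[cond]])
  })
  structure(list(recordings = recordings, layouts = layouts,
                 truth = if (length(truth)) do.call(rbind, truth) else NULL,
                 config = config),
            class = "ins_cohort")
}

# Layout matching the simulated duration: task conditions get one block
# of turn-taking phases filling the recording; rests a single task-free
# block.
condition_layout <- function(condition, duration_s, fixation_s = 30) {
  if (condition %in% c("rest", "rest_rain")) {
    return(make_rest_layout(condition, duration_s))
  }
  phase_s <- if (condition == "CI") 45 else 20
  n_turns <- max(1L, floor((duration_s - fixation_s) / (2 * phase_s)))
  build_turn_layout(condition, 1L, n_turns, phase_s, fixation_s, 0)
}

#' @rdname generate_cohort
#' @param x an `ins_cohort`.
#' @param ... ignored.
#' @export
print.ins_cohort <- function(x, ...) {
  cat(sprintf("<ins_cohort> %d dyads x {%s}, %d channels @ %g Hz\n",
              x$config$n_dyads,
              paste(names(x$recordings[[1]]), collapse = ", "),
              x$config$n_channels, x$config$sampling_rate))
  invisible(x)
}
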