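#' Lag grid for time-lagged INS
#'
#' Integer lags in seconds from `-max_lag_s` to `+max_lag_s` in steps of
#' `step_s` (default 1 s up to 26 s, i.e. 53 evaluations).  Positive lag
#' means participant C's activity trails A's: at lag `l` the analysis
#' aligns `A(t)` with `C(t + l)`.
#'
#' @param max_lag_s maximum |lag| in seconds.
#' @param step_s lag step in seconds.
#' @return integer vector of lags, symmetric around and including 0.
#' @export
lag_grid <- function(max_lag_s = 26, step_s = 1) {
  lags <- seq(-max_lag_s, max_lag_s, by = step_s)
  if (!0 %in% lags) stopf("lag grid must include 0")
  as.integer(lags)
}

# All channel pairs between two montages as a data frame (chA, chC).
all_pairs <- function(labels_A, labels_C) {
  expand.grid(chA = labels_A, chC = labels_C, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, c("chA", "chC")]
}

pair_key <- function(chA, chC) paste(chA, chC, sep = "|")

#' Channel-wise wavelet coherence between two participants
#'
#' Computes one [wtc()] coherence map per channel pair (all
#' `n_A x n_C` combinations by default; 676 for the full 26-channel
#' montage).  The per-channel wavelet transforms and smoothed power
#' fields are computed once and shared across pairs.
#'
#' @param rec_A,rec_C equal-length preprocessed [recording()]s.
#' @param grid [make_scale_grid()].
#' @param params [morlet_params()].
#' @param pairs optional data frame with columns `chA`, `chC` selecting
#'   a subset of pairs.
#' @param scale_width_oct smoothing width across scales (decades).
#' @return named list (keys `"chA|chC"`) of `coherence_map`s.
#' @export
channelwise_ins <- function(rec_A, rec_C, grid = make_scale_grid(),
                            params = grid$params, pairs = NULL,
                            scale_width_oct = 0.6) {
  if (n_samples(rec_A) != n_samples(rec_C)) stopf("recordings differ in length")
  if (rec_A$sampling_rate != rec_C$sampling_rate) stopf("sampling rates differ")
  if (is.null(pairs)) pairs <- all_pairs(rec_A$channel_labels, rec_C$channel_labels)
  bad <- !(pairs$chA %in% rec_A$channel_labels) | !(pairs$chC %in% rec_C$channel_labels)
  if (any(bad)) stopf("pair references channels outside the montage")
  rate <- rec_A$sampling_rate
  n <- n_samples(rec_A)
  ops <- smooth_ops(grid, rate, n, scale_width_oct)
  preA <- lapply(setNames(unique(pairs$chA), unique(pairs$chA)), function(ch) {
    wtc_precompute(rec_A$data[ch, ], rate, grid, params, ops)
  })
  preC <- lapply(setNames(unique(pairs$chC), unique(pairs$chC)), function(ch) {
    wtc_precompute(rec_C$data[ch, ], rate, grid, params, ops)
  })
  coi <- coi_periods(n, rate, params)
  times <- (seq_len(n) - 1L) / rate
  maps <- vector("list", nrow(pairs))
  names(maps) <- pair_key(pairs$chA, pairs$chC)
  for (i in seq_len(nrow(pairs))) {
    r2 <- wtc_from_pre(preA[[pairs$chA[i]]], preC[[pairs$chC[i]]], ops)
    maps[[i]] <- structure(list(values = r2, scale_grid = grid,
                                sampling_rate = rate, times = times, coi = coi),
                           class = "coherence_map")
  }
  maps
}

# Logical index of samples inside the layout's task blocks (half-open
# windows), given the sample times of the map.
task_sample_index <- function(times, layout) {
  keep <- rep(FALSE, length(times))
  for (b in seq_len(nrow(layout$blocks))) {
    keep <- keep | (times >= layout$blocks$start_s[b] - 1e-9 &
                    times < layout$blocks$end_s[b] - 1e-9)
  }
  keep
}

#' Average Fisher-z coherence over the task period
#'
#' Converts the coherence map to Fisher z and averages over all samples
#' that fall inside the layout's task blocks, separately per scale.
#'
#' @param coh_map a `coherence_map` from [wtc()] or [channelwise_ins()].
#' @param layout [session_layout()] on the same (re-referenced) timeline
#'   as the map.
#' @param exclude_coi drop scale/time cells under the cone of influence
#'   before averaging (default FALSE: the full map is averaged).
#' @return numeric vector of per-scale mean z values with attributes
#'   `condition` and `periods`.
#' @export
task_average <- function(coh_map, layout, exclude_coi = FALSE) {
  stopifnot(inherits(coh_map, "coherence_map"), inherits(layout, "ins_layout"))
  keep <- task_sample_index(coh_map$times, layout)
  if (!any(keep)) stopf("task period contains no samples")
  z <- fisher_z(coh_map$values[, keep, drop = FALSE])
  if (exclude_coi) {
    ok <- outer(coh_map$scale_grid$periods, coh_map$coi[keep], `<=`)
    z[!ok] <- NA_real_
    out <- rowMeans(z, na.rm = TRUE)
  } else {
    out <- rowMeans(z)
  }
  structure(out, condition = layout$condition,
            periods = coh_map$scale_grid$periods)
}

# Which rest condition is the valid baseline for a task condition.
matched_rest <- function(condition) {
  switch(condition, CI = "rest_rain", SI = "rest", CC = "rest",
         stopf("no rest baseline defined for condition %s", condition))
}

#' INS increase: task minus matched rest
#'
#' Elementwise difference of two per-scale Fisher-z averages on the same
#' scale grid.  The baseline must be the matched rest: `rest_rain` for
#' CI (rest with rain-sound masking), plain `rest` for SI and CC; a
#' mismatched pairing is an error.
#'
#' @param task_avg,rest_avg outputs of [task_average()].
#' @return per-scale INS increase with the task's attributes.
#' @export
ins_increase <- function(task_avg, rest_avg) {
  if (length(task_avg) != length(rest_avg)) stopf("scale grids differ in length")
  pt <- attr(task_avg, "periods"); pr <- attr(rest_avg, "periods")
  if (!is.null(pt) && !is.null(pr) && max(abs(pt - pr)) > 1e-9) {
    stopf("scale grids differ")
  }
  ct <- attr(task_avg, "condition"); cr <- attr(rest_avg, "condition")
  if (!is.null(ct) && !is.null(cr)) {
    if (ct %in% c("CI", "SI", "CC") && cr != matched_rest(ct)) {
      stopf("condition %s must be baselined against %s, not %s",
            ct, matched_rest(ct), cr)
    }
  }
  structure(as.numeric(task_avg) - as.numeric(rest_avg),
            condition = ct, periods = pt)
}

#' Average an INS spectrum over a frequency band
#'
#' Mean over all scales whose frequency lies in `[band[1], band[2]]` Hz
#' (equivalently periods in `[1/band[2], 1/band[1]]` s).
#'
#' @param ins_by_scale per-scale values carrying a `periods` attribute,
#'   or a plain vector with `periods` supplied.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param periods periods in seconds matching `ins_by_scale`.
#' @return scalar mean over the band.
#' @export
band_average <- function(ins_by_scale, band, periods = attr(ins_by_scale, "periods")) {
  if (is.null(periods)) stopf("no periods available for band averaging")
  if (length(band) != 2L || band[1] >= band[2]) stopf("band must be c(f_lo, f_hi)")
  f <- 1 / periods
  sel <- f >= band[1] - 1e-12 & f <= band[2] + 1e-12
  if (!any(sel)) stopf("no scales inside band [%g, %g] Hz", band[1], band[2])
  mean(as.numeric(ins_by_scale)[sel])
}

#' Per-phase Fisher-z averages with hemodynamic delay
#'
#' Averages the coherence map over each turn-taking phase, with windows
#' shifted forward by the hemodynamic delay-to-peak (~6 s by default):
#' phase `[start, start + dur)` is averaged over samples in
#' `[start + delay, start + dur + delay)`.  Windows that run past the
#' end of the record are truncated with a warning; a window entirely
#' outside is an error.
#'
#' @param coh_map a `coherence_map`.
#' @param layout [session_layout()] with turn-taking phases.
#' @param delay_s hemodynamic delay in seconds (default 6).
#' @return data frame (turn_index, phase_tag, scale_index, period_s,
#'   value) of per-phase, per-scale mean z values.
#' @export
phase_average <- function(coh_map, layout, delay_s = 6) {
  stopifnot(inherits(coh_map, "coherence_map"), inherits(layout, "ins_layout"))
  if (!nrow(layout$turns)) stopf("layout has no phases")
  z <- fisher_z(coh_map$values)
  t_end <- max(coh_map$times) + 1 / coh_map$sampling_rate
  out <- list()
  for (i in seq_len(nrow(layout$turns))) {
    ph <- layout$turns[i, ]
    w0 <- ph$start_s + delay_s
    w1 <- ph$start_s + ph$duration_s + delay_s
    if (w0 >= t_end) stopf("shifted phase window [%g, %g) is outside the record", w0, w1)
    if (w1 > t_end) {
      warnf("shifted phase window [%g, %g) truncated at record end %g s", w0, w1, t_end)
      w1 <- t_end
    }
    keep <- coh_map$times >= w0 - 1e-9 & coh_map$times < w1 - 1e-9
    if (!any(keep)) stopf("shifted phase window contains no samples")
    out[[i]] <- data.frame(turn_index = ph$turn_index, phase_tag = ph$phase_tag,
                           scale_index = seq_len(nrow(z)),
                           period_s = coh_map$scale_grid$periods,
                           value = rowMeans(z[, keep, drop = FALSE]))
  }
  do.call(rbind, out)
}

#' @rdname phase_average
#' @param phase_df output of `phase_average()`.
#' @return `phase_pool()`: data frame (phase_tag, scale_index, period_s,
#'   value) with one mean value per phase type, pooled across turns.
#' @export
phase_pool <- function(phase_df) {
  agg <- stats::aggregate(value ~ phase_tag + scale_index + period_s,
                          data = phase_df, FUN = mean)
  agg[order(agg$phase_tag, agg$scale_index), ]
}

# ---- lagged INS -------------------------------------------------------

# Shift participant C's series by `lag_s` relative to A (positive lag:
# align A(t) with C(t + lag)) and truncate both to the overlap.  A
# sample pair enters the task windows only if BOTH timelines are inside
# the window (A at `s`, C at `s + lag`), so each window shrinks by |lag|
# at one end; this makes exchanging the roles of A and C exactly
# equivalent to negating the lag.
shift_pair <- function(rec_A, rec_C, layout, lag_s) {
  rate <- rec_A$sampling_rate
  k <- lag_s * rate
  if (abs(k - round(k)) > 1e-9) stopf("lag %g s is not a whole number of samples", lag_s)
  k <- as.integer(round(k))
  n <- n_samples(rec_A)
  if (abs(k) >= n) stopf("lag %g s leaves no overlap", lag_s)
  A <- rec_A; C <- rec_C
  if (k >= 0) {
    keepA <- seq_len(n - k); keepC <- seq.int(k + 1L, n)
    seg_start <- 0
  } else {
    keepA <- seq.int(-k + 1L, n); keepC <- seq_len(n + k)
    seg_start <- -k / rate
  }
  A$data <- rec_A$data[, keepA, drop = FALSE]
  C$data <- rec_C$data[, keepC, drop = FALSE]
  # windows in segment coordinates: [start - seg_start, end - seg_start),
  # with the end pulled in by |lag| so the C-side timeline stays inside
  lay <- layout
  lay$blocks$start_s <- layout$blocks$start_s + max(0, -lag_s) - seg_start
  lay$blocks$end_s <- layout$blocks$end_s - max(0, lag_s) - seg_start
  lay$blocks <- lay$blocks[lay$blocks$end_s > lay$blocks$start_s, , drop = FALSE]
  if (!nrow(lay$blocks)) stopf("lag %g s leaves no task window", lag_s)
  if (nrow(lay$turns)) {
    lay$turns$start_s <- layout$turns$start_s + max(0, -lag_s) - seg_start
    lay$turns$duration_s <- layout$turns$duration_s - abs(lag_s)
    lay$turns <- lay$turns[lay$turns$duration_s > 0, , drop = FALSE]
  }
  lay <- shift_layout(lay, 0, clip_to_s = length(keepA) / rate)
  list(A = A, C = C, layout = lay)
}

# Per-scale task-averaged Fisher-z spectra for a set of channel pairs,
# sharing per-channel transforms: returns scales x pairs matrix.
ins_spectra <- function(rec_A, rec_C, layout, grid, params, pairs,
                        scale_width_oct = 0.6, exclude_coi = FALSE) {
  maps <- channelwise_ins(rec_A, rec_C, grid, params, pairs, scale_width_oct)
  out <- vapply(maps, function(m) as.numeric(task_average(m, layout, exclude_coi)),
                numeric(grid$n_scales))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(maps),
                                       dimnames = list(NULL, names(maps)))
  out
}

#' Time-lagged INS increase for one dyad and condition
#'
#' For every lag in `lags_s`, participant C's series is shifted in the
#' time domain, both series are truncated to the overlap, the full
#' wavelet coherence is recomputed, task-averaged, and baselined against
#' the matched rest (shifted and truncated identically).  Lag 0
#' reproduces the unlagged pipeline exactly.
#'
#' @param rec_A,rec_C preprocessed task recordings of the two
#'   participants.
#' @param layout task [session_layout()] (already re-referenced for any
#'   trimming).
#' @param rest_A,rest_C preprocessed matched-rest recordings.
#' @param rest_layout rest layout.
#' @param lags_s integer lags in seconds, see [lag_grid()].
#' @param grid,params wavelet configuration.
#' @param pairs data frame (chA, chC); default all pairs.
#' @param dyad_id identifier stored in the output table.
#' @param scale_width_oct smoothing width across scales.
#' @param lag_rest also delay and truncate the rest recordings at every
#'   lag (default FALSE: the rest baseline carries no coupling
#'   structure, so delaying it cannot reveal anything — it only adds an
#'   independent noise term to every lag and doubles the computation;
#'   the baseline is therefore evaluated once, unlagged).
#' @return an [ins_table()] with one row per (pair, scale, lag).
#' @export
lagged_ins <- function(rec_A, rec_C, layout, rest_A, rest_C, rest_layout,
                       lags_s = lag_grid(), grid = make_scale_grid(),
                       params = grid$params, pairs = NULL, dyad_id = "dyad01",
                       scale_width_oct = 0.6, lag_rest = FALSE) {
  if (is.null(pairs)) pairs <- all_pairs(rec_A$channel_labels, rec_C$channel_labels)
  condition <- layout$condition
  if (rest_layout$condition != matched_rest(condition)) {
    stopf("condition %s must be baselined against %s, not %s",
          condition, matched_rest(condition), rest_layout$condition)
  }
  rate <- rec_A$sampling_rate
  rest_z0 <- if (!lag_rest) {
    ins_spectra(rest_A, rest_C, rest_layout, grid, params, pairs, scale_width_oct)
  }
  rows <- list()
  for (lg in lags_s) {
    st <- shift_pair(rec_A, rec_C, layout, lg)
    n_overlap <- n_samples(st$A)
    if (n_overlap / rate < 60) stopf("overlap of %.1f s at lag %d s is shorter than 60 s",
                                     n_overlap / rate, lg)
    if (n_overlap / rate < 2 * max(grid$periods)) {
      warnf("overlap of %.1f s at lag %d s is short for max period %.1f s",
            n_overlap / rate, lg, max(grid$periods))
    }
    task_z <- ins_spectra(st$A, st$C, st$layout, grid, params, pairs, scale_width_oct)
    rest_z <- if (lag_rest) {
      sr <- shift_pair(rest_A, rest_C, rest_layout, lg)
      ins_spectra(sr$A, sr$C, sr$layout, grid, params, pairs, scale_width_oct)
    } else {
      rest_z0
    }
    inc <- task_z - rest_z
    for (i in seq_len(nrow(pairs))) {
      rows[[length(rows) + 1L]] <- data.frame(
        dyad = dyad_id, condition = condition,
        chA = pairs$chA[i], chC = pairs$chC[i],
        scale_index = seq_len(grid$n_scales), period_s = grid$periods,
        lag_s = lg, value = inc[, i])
    }
  }
  ins_table(do.call(rbind, rows), max_lag_s = max(abs(lags_s)))
}

#' Preprocess a recording for coherence analysis
#'
#' The standard chain: trim the unstable edges (30 s each side),
#' remove the linear trend, and repair motion artifacts with [tddr()].
#' No band-pass filtering is applied: frequency selection happens after
#' coherence, through the scale axis of the wavelet transform.
#'
#' @param rec an [recording()].
#' @param trim_s edge trim in seconds.
#' @param params [tddr_params()], or NULL to skip TDDR.
#' @return preprocessed `ins_recording`.
#' @export
preprocess_recording <- function(rec, trim_s = 30, params = tddr_params()) {
  out <- trim_edges(rec, trim_s)
  out <- detrend(out)
  if (!is.null(params)) out <- tddr(out, params)
  out
}

#' Full INS-increase table for a simulated cohort
#'
#' Runs preprocessing, channel-wise (optionally lagged) wavelet
#' coherence, task averaging and rest subtraction for every dyad and
#' task condition in a cohort, producing the long INS table the group
#' statistics consume.
#'
#' @param cohort an `ins_cohort` from [generate_cohort()].
#' @param grid,params wavelet configuration.
#' @param pairs data frame (chA, chC); default all pairs.
#' @param lags_s integer lags in seconds (default 0 only).
#' @param trim_s edge trim in seconds (default 30).
#' @param tddr_par [tddr_params()], or NULL to skip motion correction.
#' @param scale_width_oct smoothing width across scales.
#' @param lag_rest see [lagged_ins()].
#' @return an [ins_table()].
#' @export
cohort_ins <- function(cohort, grid = make_scale_grid(), params = grid$params,
                       pairs = NULL, lags_s = 0L, trim_s = 30,
                       tddr_par = tddr_params(), scale_width_oct = 0.6,
                       lag_rest = FALSE) {
  stopifnot(inherits(cohort, "ins_cohort"))
  conds <- setdiff(names(cohort$layouts), c("rest", "rest_rain"))
  rows <- list()
  for (d in names(cohort$recordings)) {
    pre <- list()   # preprocessed recordings cache per condition
    for (cond in names(cohort$recordings[[d]])) {
      pre[[cond]] <- list(
        A = preprocess_recording(cohort$recordings[[d]][[cond]]$A, trim_s, tddr_par),
        C = preprocess_recording(cohort$recordings[[d]][[cond]]$C, trim_s, tddr_par))
    }
    for (cond in conds) {
      rest <- matched_rest(cond)
      if (!rest %in% names(cohort$recordings[[d]])) {
        stopf("condition %s requires the matched rest baseline '%s' (%s)",
              cond, rest,
              if (rest == "rest_rain") "resting state with rain sounds" else
                "plain resting state")
      }
      lay_task <- shift_layout(cohort$layouts[[cond]], -trim_s,
                               duration_s(pre[[cond]]$A))
      lay_rest <- shift_layout(cohort$layouts[[rest]], -trim_s,
                               duration_s(pre[[rest]]$A))
      rows[[length(rows) + 1L]] <- lagged_ins(
        pre[[cond]]$A, pre[[cond]]$C, lay_task,
        pre[[rest]]$A, pre[[rest]]$C, lay_rest,
        lags_s = lags_s, grid = grid, params = params, pairs = pairs,
        dyad_id = d, scale_width_oct = scale_width_oct, lag_rest = lag_rest)
    }
  }
  ins_table(do.call(rbind, rows), max_lag_s = max(abs(lags_s)))
}

#' Collapse an INS table over a frequency band
#'
#' @param table an [ins_table()].
#' @param band `c(f_lo, f_hi)` in Hz.
#' @return data frame (dyad, condition, chA, chC, lag_s, value) with the
#'   scale axis averaged over the band.
#' @export
band_average_ins <- function(table, band) {
  sel <- 1 / table$period_s >= band[1] - 1e-12 & 1 / table$period_s <= band[2] + 1e-12
  if (!any(sel)) stopf("no scales inside band [%g, %g] Hz", band[1], band[2])
  sub <- table[sel, , drop = FALSE]
  stats::aggregate(value ~ dyad + condition + chA + chC + lag_s,
                   data = sub, FUN = mean)
}
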