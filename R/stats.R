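#' Per-scale repeated-measures F statistics across conditions
#'
#' One-way repeated-measures ANOVA at each wavelet scale: dyads are the
#' repeated-measures unit, conditions the within factor.  With two
#' conditions the statistic equals the squared paired t.  The degenerate
#' all-zero case (identical condition means and zero within-dyad
#' variability, 0/0) returns 0 with a warning.
#'
#' @param ins_spectra data frame with columns `dyad`, `condition`,
#'   `scale_index`, `value`: per-dyad, per-scale INS (band-unaveraged),
#'   every dyad measured in every condition.
#' @return numeric vector of F values, one per scale, with attribute
#'   `df` (numerator, denominator degrees of freedom).
#' @export
frequency_f_stats <- function(ins_spectra) {
  V <- spectra_array(ins_spectra)
  f <- unname(rm_anova_f(V))
  if (any(!is.finite(f) | f < 0)) {
    warnf("degenerate scales (zero between- and within-dyad variance): F set to 0")
    f[!is.finite(f)] <- 0
  }
  structure(f, df = c(dim(V)[2] - 1L, (dim(V)[2] - 1L) * (dim(V)[1] - 1L)))
}

# Long data frame -> array [dyad, condition, scale].
spectra_array <- function(df) {
  need <- c("dyad", "condition", "scale_index", "value")
  stopifnot(all(need %in% names(df)))
  dyads <- sort(unique(df$dyad))
  conds <- sort(unique(df$condition))
  scales <- sort(unique(df$scale_index))
  if (length(dyads) < 2L) stopf("need >= 2 dyads")
  if (length(conds) < 2L) stopf("need >= 2 conditions")
  V <- array(NA_real_, c(length(dyads), length(conds), length(scales)),
             dimnames = list(dyads, conds, scales))
  V[cbind(match(df$dyad, dyads), match(df$condition, conds),
          match(df$scale_index, scales))] <- df$value
  if (anyNA(V)) stopf("unbalanced design: every dyad needs every condition at every scale")
  V
}

# Vectorised RM-ANOVA F over the scale axis of [dyad, condition, scale].
rm_anova_f <- function(V) {
  nd <- dim(V)[1]; nc <- dim(V)[2]; ns <- dim(V)[3]
  cm <- apply(V, c(2, 3), mean)             # condition means  [c, s]
  dm <- apply(V, c(1, 3), mean)             # dyad means       [d, s]
  gm <- colMeans(cm)                        # grand means      [s]
  ss_cond <- nd * colSums((cm - rep(gm, each = nc))^2)
  resid <- V -
    aperm(array(cm, c(nc, ns, nd)), c(3, 1, 2)) -
    aperm(array(dm, c(nd, ns, nc)), c(1, 3, 2)) +
    aperm(array(gm, c(ns, nd, nc)), c(2, 3, 1))
  ss_err <- apply(resid^2, 3, sum)
  ms_cond <- ss_cond / (nc - 1)
  ms_err <- ss_err / ((nc - 1) * (nd - 1))
  f <- ms_cond / ms_err
  f[ms_cond == 0 & ms_err == 0] <- NaN      # 0/0, flagged by the caller
  f
}

#' Maximal runs of scales exceeding a threshold
#'
#' @param f numeric vector (e.g. per-scale F values).
#' @param threshold scalar.
#' @return list of integer vectors `c(start, end)` (1-based, inclusive).
#' @examples
#' exceedance_clusters(c(1, 5, 6, 2, 7, 8, 9, 1), 4)
#' @export
exceedance_clusters <- function(f, threshold) {
  above <- f > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i]) out[[length(out) + 1L]] <- c(starts[i], ends[i])
  }
  out
}

# Merge clusters whose separation (start of next minus end of previous,
# in scale steps) is below `merge_gap` steps.
merge_clusters <- function(clusters, merge_gap = 2L) {
  if (length(clusters) < 2L) return(clusters)
  out <- list(clusters[[1]])
  for (cl in clusters[-1]) {
    last <- out[[length(out)]]
    if (cl[1] - last[2] < merge_gap) {
      out[[length(out)]] <- c(last[1], cl[2])
    } else {
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' Permutation selection of frequency bands of interest
#'
#' Permutation test over the frequency axis: condition labels are
#' shuffled within each dyad independently (`n_perm` times, default
#' 1000); each permutation's null statistic is the maximum per-scale F
#' across scales (family-wise control over frequencies; a pointwise
#' per-scale null is available via `family = "pointwise"`).  Scales
#' whose original F exceeds the `percentile`-th percentile (default
#' 99th, significance 0.01) of the null form contiguous clusters;
#' clusters closer than `merge_gap` scale steps are merged into single
#' bands.
#'
#' @param ins_spectra as in [frequency_f_stats()].
#' @param n_perm number of permutations (warning below 100).
#' @param percentile null percentile defining the threshold.
#' @param seed integer seed (required: permutations must be
#'   reproducible).
#' @param family `"max"` (max-F across scales) or `"pointwise"`.
#' @param merge_gap cluster-merging distance in scale steps.
#' @param periods optional per-scale periods (seconds) used to report
#'   band edges in Hz; taken from `ins_spectra$period_s` if present.
#' @return list of class `band_selection`: `f_values`, `threshold`,
#'   `clusters` (scale-index ranges), `merged_bands` (data frame with
#'   `f_lo`, `f_hi` in Hz and period bounds, when periods are known),
#'   `null_max` (the permutation distribution).
#' @export
permutation_band_selection <- function(ins_spectra, n_perm = 1000,
                                       percentile = 99, seed = NULL,
                                       family = c("max", "pointwise"),
                                       merge_gap = 2L, periods = NULL) {
  family <- match.arg(family)
  if (n_perm < 100) warnf("n_perm = %d is small; percentile estimates will be coarse", n_perm)
  if (is.null(seed)) stopf("a seed is required for a reproducible permutation test")
  V <- spectra_array(ins_spectra)
  if (is.null(periods) && "period_s" %in% names(ins_spectra)) {
    key <- !duplicated(ins_spectra$scale_index)
    periods <- ins_spectra$period_s[key][order(ins_spectra$scale_index[key])]
  }
  f_orig <- rm_anova_f(V)
  f_orig[!is.finite(f_orig)] <- 0
  nd <- dim(V)[1]; nc <- dim(V)[2]; ns <- dim(V)[3]
  null_stat <- with_seed(seed, {
    m <- matrix(NA_real_, n_perm, if (family == "max") 1L else ns)
    for (p in seq_len(n_perm)) {
      Vp <- V
      for (d in seq_len(nd)) Vp[d, , ] <- V[d, sample.int(nc), ]
      fp <- rm_anova_f(Vp)
      fp[!is.finite(fp)] <- 0
      m[p, ] <- if (family == "max") max(fp) else fp
    }
    m
  })
  if (family == "max") {
    threshold <- as.numeric(quantile(null_stat[, 1], percentile / 100))
    above <- f_orig > threshold
  } else {
    threshold <- apply(null_stat, 2, quantile, probs = percentile / 100)
    above <- f_orig > threshold
  }
  clusters <- exceedance_clusters(as.numeric(above), 0.5)
  merged <- merge_clusters(clusters, merge_gap)
  bands <- NULL
  if (!is.null(periods) && length(merged)) {
    bands <- do.call(rbind, lapply(merged, function(cl) {
      per <- periods[cl[1]:cl[2]]
      data.frame(scale_lo = cl[1], scale_hi = cl[2],
                 period_lo_s = min(per), period_hi_s = max(per),
                 f_lo = 1 / max(per), f_hi = 1 / min(per))
    }))
  }
  structure(list(f_values = f_orig, threshold = threshold,
                 clusters = clusters, merged_bands = bands,
                 merged_clusters = merged,
                 null_max = if (family == "max") null_stat[, 1] else null_stat,
                 n_perm = n_perm, percentile = percentile, family = family),
            class = "band_selection")
}

#' @rdname permutation_band_selection
#' @param x a `band_selection`.
#' @param ... ignored.
#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("<band_selection> %d permutation(s), %gth percentile threshold %.3f\n",
              x$n_perm, x$percentile, x$threshold[1]))
  if (is.null(x$merged_bands) || !nrow(x$merged_bands)) {
    cat("  no bands selected\n")
  } else {
    for (i in seq_len(nrow(x$merged_bands))) {
      b <- x$merged_bands[i, ]
      cat(sprintf("  band %d: %.3f-%.3f Hz (periods %.1f-%.1f s)\n", i,
                  b$f_lo, b$f_hi, b$period_lo_s, b$period_hi_s))
    }
  }
  invisible(x)
}

#' Paired t-tests over channel pairs and lags with Bonferroni correction
#'
#' For every (channel pair, lag) cell present in both tables, a paired
#' two-sided t-test of the band-averaged INS increase between the two
#' conditions, Bonferroni-corrected for the full family
#' `m = n_pairs * n_lags` at level `alpha`.
#'
#' @param ins_a,ins_b band-averaged tables (data frames with `dyad`,
#'   `chA`, `chC`, `lag_s`, `value`), e.g. from [band_average_ins()];
#'   same dyads in both.
#' @param alpha family-wise significance level (default 0.05).
#' @return data frame (chA, chC, lag_s, n, mean_diff, t, p, p_bonf,
#'   significant) of class `group_test`, with attributes `m` and
#'   `alpha`.
#' @export
paired_condition_test <- function(ins_a, ins_b, alpha = 0.05) {
  dy_a <- sort(unique(ins_a$dyad)); dy_b <- sort(unique(ins_b$dyad))
  if (!identical(dy_a, dy_b)) stopf("dyads differ between the two conditions")
  if (length(dy_a) < 3L) stopf("need >= 3 dyads for a paired t-test")
  merged <- merge(ins_a, ins_b, by = c("dyad", "chA", "chC", "lag_s"),
                  suffixes = c("_a", "_b"))
  if (!nrow(merged)) stopf("tables share no (dyad, pair, lag) cells")
  merged$diff <- merged$value_a - merged$value_b
  key <- paste(merged$chA, merged$chC, merged$lag_s, sep = "|")
  # cells x dyads matrix of differences (vectorised: the full scan has
  # n_pairs * n_lags cells)
  if (anyDuplicated(paste(key, merged$dyad))) {
    stopf("duplicate (dyad, pair, lag) rows: band-average first")
  }
  D <- tapply(merged$diff, list(key, merged$dyad), mean)
  if (anyNA(D)) stopf("unbalanced tables: every dyad needs every (pair, lag) cell")
  n <- ncol(D)
  mean_d <- rowMeans(D)
  sd_d <- sqrt(rowSums((D - mean_d)^2) / (n - 1))
  tval <- ifelse(sd_d == 0, ifelse(mean_d == 0, 0, sign(mean_d) * Inf),
                 mean_d / (sd_d / sqrt(n)))
  first <- match(rownames(D), key)
  out <- data.frame(chA = merged$chA[first], chC = merged$chC[first],
                    lag_s = merged$lag_s[first], n = n, mean_diff = mean_d,
                    t = tval, p = 2 * pt(-abs(tval), n - 1))
  rownames(out) <- NULL
  m <- length(unique(paste(out$chA, out$chC))) * length(unique(out$lag_s))
  out$p_bonf <- pmin(out$p * m, 1)
  out$significant <- out$p < alpha / m
  out <- out[order(out$p), ]
  structure(out, m = m, alpha = alpha,
            class = c("group_test", "data.frame"))
}

# All permutations of 1..n (n small), as a matrix with one row each.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Pseudo-dyad permutation validation of an INS effect
#'
#' The standard hyperscanning null: participant A of each dyad is
#' re-paired with participant C of another dyad, and the group-mean
#' condition difference of the band-averaged INS increase at the target
#' channel pair and lag is recomputed for each pseudo-pairing.  The
#' observed (true-pairing) statistic is then located in that null
#' distribution; it is flagged significant when it falls outside the
#' central `1 - two_tailed_area` region.
#'
#' For small cohorts the null is enumerated exhaustively over all
#' `n_dyads!` pairings (including the identity); otherwise `n_perm`
#' random pairings are sampled (with replacement when `n_perm` exceeds
#' the number of distinct pairings, noted in the output).
#'
#' @param cohort an `ins_cohort` from [generate_cohort()].
#' @param target_pair `c(chA, chC)` channel labels.
#' @param target_lag_s integer lag in seconds.
#' @param band `c(f_lo, f_hi)` Hz for band averaging.
#' @param conditions the two conditions contrasted (default CI - SI).
#' @param n_perm number of permutations when not exhaustive.
#' @param seed integer seed (required unless exhaustive).
#' @param two_tailed_area total tail area for the significance flag.
#' @param exhaustive force (TRUE) or forbid (FALSE) exhaustive
#'   enumeration; default enumerates when `n_dyads! <= n_perm`.
#' @param grid,params,trim_s,tddr_par,scale_width_oct pipeline settings,
#'   as in [cohort_ins()].
#' @return list of class `pseudo_pair_test`: `observed`, `null`,
#'   `p_two_tailed`, `significant`, `method`, `cross_matrix` per
#'   condition.
#' @export
pseudo_pair_permutation <- function(cohort, target_pair, target_lag_s = 0,
                                    band, conditions = c("CI", "SI"),
                                    n_perm = 1000, seed = NULL,
                                    two_tailed_area = 0.05,
                                    exhaustive = NULL,
                                    grid = make_scale_grid(),
                                    params = grid$params, trim_s = 30,
                                    tddr_par = tddr_params(),
                                    scale_width_oct = 0.6) {
  stopifnot(inherits(cohort, "ins_cohort"), length(target_pair) == 2L,
            length(conditions) == 2L)
  nd <- cohort$config$n_dyads
  if (nd < 4 && is.null(exhaustive)) exhaustive <- TRUE
  dyads <- names(cohort$recordings)
  # cross INS matrices: M[i, j] = band-averaged INS increase between
  # A of dyad i and C of dyad j (task and rest crossed identically)
  M <- lapply(setNames(conditions, conditions), function(cond) {
    cross_ins_matrix(cohort, cond, target_pair, target_lag_s, band,
                     grid, params, trim_s, tddr_par, scale_width_oct)
  })
  D <- M[[conditions[1]]] - M[[conditions[2]]]
  observed <- mean(diag(D))
  n_distinct <- factorial(nd)
  use_exhaustive <- isTRUE(exhaustive) ||
    (is.null(exhaustive) && n_distinct <= n_perm && nd <= 8)
  note <- NULL
  if (use_exhaustive) {
    perms <- all_permutations(nd)
    method <- "exhaustive"
  } else {
    if (is.null(seed)) stopf("a seed is required for sampled permutations")
    if (n_perm > n_distinct) {
      note <- sprintf("n_perm = %d exceeds the %d distinct re-pairings; sampling with replacement",
                      n_perm, n_distinct)
      warnf("%s", note)
    }
    perms <- with_seed(seed, t(replicate(n_perm, sample.int(nd))))
    method <- "sampled"
  }
  null <- apply(perms, 1, function(pp) mean(D[cbind(seq_len(nd), pp)]))
  p_two <- min(1, 2 * min(mean(null <= observed), mean(null >= observed)))
  qs <- quantile(null, c(two_tailed_area / 2, 1 - two_tailed_area / 2))
  structure(list(observed = observed, null = null, p_two_tailed = p_two,
                 significant = observed < qs[1] || observed > qs[2],
                 quantiles = qs, method = method, note = note,
                 cross_matrix = M, conditions = conditions),
            class = "pseudo_pair_test")
}

# Band-averaged INS increase between every A_i and C_j combination at
# one channel pair and lag.  Shares preprocessing and per-participant
# wavelet transforms across the n^2 combinations.
cross_ins_matrix <- function(cohort, condition, target_pair, lag_s, band,
                             grid, params, trim_s, tddr_par, scale_width_oct) {
  dyads <- names(cohort$recordings)
  rest <- matched_rest(condition)
  pre <- lapply(setNames(dyads, dyads), function(d) {
    list(A = preprocess_recording(cohort$recordings[[d]][[condition]]$A, trim_s, tddr_par),
         C = preprocess_recording(cohort$recordings[[d]][[condition]]$C, trim_s, tddr_par),
         rA = preprocess_recording(cohort$recordings[[d]][[rest]]$A, trim_s, tddr_par),
         rC = preprocess_recording(cohort$recordings[[d]][[rest]]$C, trim_s, tddr_par))
  })
  lay_task <- shift_layout(cohort$layouts[[condition]], -trim_s,
                           duration_s(pre[[1]]$A))
  lay_rest <- shift_layout(cohort$layouts[[rest]], -trim_s,
                           duration_s(pre[[1]]$rA))
  band_cross <- function(recs_A, recs_C, layout, lag_s) {
    rate <- recs_A[[1]]$sampling_rate
    n <- n_samples(recs_A[[1]])
    k <- as.integer(round(lag_s * rate))
    if (k >= 0) { keepA <- seq_len(n - k); keepC <- seq.int(k + 1L, n) }
    else { keepA <- seq.int(-k + 1L, n); keepC <- seq_len(n + k) }
    # same truncation and window convention as shift_pair()
    lay <- shift_pair(recs_A[[1]], recs_C[[1]], layout, lag_s)$layout
    ops <- smooth_ops(grid, rate, length(keepA), scale_width_oct)
    preA <- lapply(recs_A, function(r)
      wtc_precompute(r$data[target_pair[1], keepA], rate, grid, params, ops))
    preC <- lapply(recs_C, function(r)
      wtc_precompute(r$data[target_pair[2], keepC], rate, grid, params, ops))
    coi <- coi_periods(length(keepA), rate, params)
    times <- (seq_along(keepA) - 1L) / rate
    m <- matrix(NA_real_, length(recs_A), length(recs_C))
    for (i in seq_along(recs_A)) {
      for (j in seq_along(recs_C)) {
        r2 <- wtc_from_pre(preA[[i]], preC[[j]], ops)
        map <- structure(list(values = r2, scale_grid = grid,
                              sampling_rate = rate, times = times, coi = coi),
                         class = "coherence_map")
        m[i, j] <- band_average(task_average(map, lay), band)
      }
    }
    m
  }
  task <- band_cross(lapply(pre, `[[`, "A"), lapply(pre, `[[`, "C"), lay_task,
                     lag_s)
  # the coupling-free baseline is evaluated unlagged (see lagged_ins)
  rst <- band_cross(lapply(pre, `[[`, "rA"), lapply(pre, `[[`, "rC"), lay_rest,
                    0)
  task - rst
}

#' Pearson correlation between phase-wise INS and behavioural scores
#'
#' @param phase_ins numeric vector of per-dyad INS values (e.g. pooled
#'   phase averages), optionally named by dyad.
#' @param scores numeric vector of per-dyad scores, aligned by name when
#'   both are named.
#' @return list with `r`, `p` (two-sided), `n`, `df`.
#' @export
score_correlation <- function(phase_ins, scores) {
  if (!is.null(names(phase_ins)) && !is.null(names(scores))) {
    common <- intersect(names(phase_ins), names(scores))
    phase_ins <- phase_ins[common]; scores <- scores[common]
  }
  ok <- is.finite(phase_ins) & is.finite(scores)
  x <- phase_ins[ok]; y <- scores[ok]
  if (length(x) < 3L) stopf("need >= 3 dyads with both INS and score")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), n - 2), n = n, df = n - 2L)
}
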