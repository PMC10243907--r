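spectra_df <- function(mat_by_cond, periods = NULL) {
  # mat_by_cond: named list of dyad x scale matrices
  rows <- list()
  for (cond in names(mat_by_cond)) {
    m <- mat_by_cond[[cond]]
    for (d in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <- data.frame(
        dyad = sprintf("d%02d", d), condition = cond,
        scale_index = seq_len(ncol(m)),
        period_s = if (is.null(periods)) seq_len(ncol(m)) else periods,
        value = m[d, ])
    }
  }
  do.call(rbind, rows)
}

test_that("the repeated-measures F matches aov and equals t^2 for two conditions", {
  set.seed(12)
  a <- matrix(rnorm(6 * 5), 6)
  b <- matrix(rnorm(6 * 5, 0.4), 6)
  f <- frequency_f_stats(spectra_df(list(CI = a, SI = b)))
  expect_equal(attr(f, "df"), c(1L, 5L))
  for (j in 1:5) {
    tt <- t.test(a[, j], b[, j], paired = TRUE)
    expect_equal(f[j], unname(tt$statistic)^2, tolerance = 1e-9)
  }

  # three conditions against the aov oracle
  cc <- matrix(rnorm(6 * 5, 0.2), 6)
  f3 <- frequency_f_stats(spectra_df(list(CI = a, SI = b, CC = cc)))
  for (j in 1:5) {
    df <- data.frame(v = c(a[, j], b[, j], cc[, j]),
                     cond = rep(c("CI", "SI", "CC"), each = 6),
                     dyad = factor(rep(1:6, 3)))
    want <- summary(aov(v ~ cond + dyad, df))[[1]]["cond", "F value"]
    expect_equal(f3[j], want, tolerance = 1e-9)
  }

  # hand-computable 3-dyad, 2-condition toy table
  x <- c(1, 2, 3); y <- c(2, 4, 3)
  fh <- frequency_f_stats(spectra_df(list(CI = matrix(x), SI = matrix(y))))
  d <- y - x                                   # diffs {1, 2, 0}
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(as.numeric(fh), t_hand^2, tolerance = 1e-12)

  # degenerate all-equal table
  z <- matrix(1, 3, 2)
  expect_warning(f0 <- frequency_f_stats(spectra_df(list(CI = z, SI = z))),
                 "degenerate")
  expect_equal(as.numeric(f0), c(0, 0))
})

test_that("exceedance clusters and merging follow the run structure", {
  cl <- exceedance_clusters(c(1, 5, 6, 2, 7, 8, 9, 1), 4)
  expect_equal(cl, list(c(2L, 3L), c(5L, 7L)))
  expect_equal(exceedance_clusters(c(1, 1), 4), list())
  expect_equal(exceedance_clusters(c(9, 9), 4), list(c(1L, 2L)))

  # separation of 2 steps stays split at merge_gap 2, merges at 3
  expect_length(insync:::merge_clusters(cl, 2), 2)
  merged <- insync:::merge_clusters(cl, 3)
  expect_equal(merged, list(c(2L, 7L)))
})

test_that("permutation band selection finds an injected condition effect", {
  set.seed(40)
  n_s <- 40
  periods <- exp(seq(log(10), log(80), length.out = n_s))
  eff <- periods >= 31.25 & periods <= 50
  a <- matrix(rnorm(10 * n_s), 10)
  b <- matrix(rnorm(10 * n_s), 10)
  b[, eff] <- b[, eff] + 3
  sel <- permutation_band_selection(spectra_df(list(CI = a, SI = b), periods),
                                    n_perm = 300, seed = 77)
  expect_s3_class(sel, "band_selection")
  expect_gte(nrow(sel$merged_bands), 1)
  hit <- any(sel$merged_bands$f_lo <= 0.032 & sel$merged_bands$f_hi >= 0.020)
  expect_true(hit)
  expect_error(permutation_band_selection(
    spectra_df(list(CI = a, SI = b), periods), n_perm = 300), "seed")
  expect_warning(permutation_band_selection(
    spectra_df(list(CI = a, SI = b), periods), n_perm = 50, seed = 1), "small")
})

test_that("paired condition tests match the t-test oracle cell by cell", {
  make_tab <- function(vals, dyads = sprintf("d%02d", seq_along(vals))) {
    data.frame(dyad = dyads, chA = "CH1", chC = "CH2", lag_s = 0,
               value = vals)
  }
  # all-zero differences
  r0 <- paired_condition_test(make_tab(c(1, 2, 3)), make_tab(c(1, 2, 3)))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # differences {1, 2, 3}: t = 2 * sqrt(3), p from t(2)
  r <- paired_condition_test(make_tab(c(2, 4, 6)), make_tab(c(1, 2, 3)))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)

  # random multi-cell scan against stats::t.test
  set.seed(13)
  cells <- expand.grid(chA = c("CH1", "CH2"), chC = c("CH1", "CH2"),
                       lag_s = c(-1, 0, 1), stringsAsFactors = FALSE)
  ta <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(dyad = sprintf("d%02d", 1:6), chA = cells$chA[i],
               chC = cells$chC[i], lag_s = cells$lag_s[i], value = rnorm(6))
  }))
  tb <- transform(ta, value = rnorm(nrow(ta), 0.3))
  res <- paired_condition_test(ta, tb)
  expect_equal(attr(res, "m"), 4 * 3)
  for (i in seq_len(nrow(res))) {
    va <- ta$value[ta$chA == res$chA[i] & ta$chC == res$chC[i] & ta$lag_s == res$lag_s[i]]
    vb <- tb$value[tb$chA == res$chA[i] & tb$chC == res$chC[i] & tb$lag_s == res$lag_s[i]]
    tt <- t.test(va, vb, paired = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-9)
  }
  expect_true(all(res$significant == (res$p < 0.05 / 12)))

  # the full default scan family size
  expect_equal(26 * 26 * length(lag_grid(26)), 35828)

  expect_error(paired_condition_test(make_tab(c(1, 2)), make_tab(c(1, 2))),
               ">= 3 dyads")
  expect_error(paired_condition_test(make_tab(c(1, 2, 3)),
                                     make_tab(c(1, 2, 3),
                                              dyads = c("x", "y", "z"))),
               "dyads differ")
})

test_that("Bonferroni correction is monotone in the family size", {
  set.seed(14)
  base <- data.frame(dyad = sprintf("d%02d", 1:8), chA = "CH1", chC = "CH1",
                     lag_s = 0, value = rnorm(8, 0.8))
  rest <- data.frame(dyad = sprintf("d%02d", 1:8), chA = "CH1", chC = "CH1",
                     lag_s = 0, value = rnorm(8))
  small <- paired_condition_test(base, rest)
  wide_a <- rbind(base, transform(base, lag_s = 1, value = rnorm(8)),
                  transform(base, lag_s = 2, value = rnorm(8)))
  wide_b <- rbind(rest, transform(rest, lag_s = 1, value = rnorm(8)),
                  transform(rest, lag_s = 2, value = rnorm(8)))
  wide <- paired_condition_test(wide_a, wide_b)
  cell <- wide[wide$lag_s == 0, ]
  # enlarging the family can only lose significance, never gain it
  expect_true(!cell$significant || small$significant)
  expect_gte(cell$p_bonf, small$p_bonf)
})

test_that("pseudo-dyad permutation matches exhaustive enumeration", {
  cfg <- sim_config(n_dyads = 3, n_channels = 1, duration_s = 150,
                    couplings = list(coupling_spec("CH1", "CH1", 0.05, 0.012,
                                                   0, 0.8, "SI")),
                    artifacts = artifact_spec(0, 6, 0, 2),
                    strength_jitter_sd = 0, seed = 19)
  co <- generate_cohort(cfg)
  g <- make_scale_grid(4, 40, 16)
  res <- pseudo_pair_permutation(co, c("CH1", "CH1"), 0, band = c(0.04, 0.0666),
                                 conditions = c("SI", "CI"), grid = g,
                                 trim_s = 20, n_perm = 10)
  expect_equal(res$method, "exhaustive")
  expect_length(res$null, 6)                    # 3! pairings incl. identity
  # brute-force oracle over the returned cross matrices
  D <- res$cross_matrix$SI - res$cross_matrix$CI
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  want <- sort(vapply(perms, function(p) mean(D[cbind(1:3, p)]), numeric(1)))
  expect_equal(sort(res$null), want, tolerance = 1e-12)
  # the observed statistic is one element of the null (identity pairing)
  expect_true(any(abs(res$null - res$observed) < 1e-12))

  # a strong true-pair-only coupling is detected as extreme
  cfg5 <- sim_config(n_dyads = 5, n_channels = 1, duration_s = 200,
                     couplings = list(coupling_spec("CH1", "CH1", 0.05, 0.012,
                                                    0, 0.85, "SI")),
                     artifacts = artifact_spec(0, 6, 0, 2),
                     strength_jitter_sd = 0.05, seed = 23)
  co5 <- generate_cohort(cfg5)
  res5 <- pseudo_pair_permutation(co5, c("CH1", "CH1"), 0,
                                  band = c(0.04, 0.0666),
                                  conditions = c("SI", "CI"), grid = g,
                                  trim_s = 20, n_perm = 120)
  expect_equal(res5$method, "exhaustive")
  expect_true(res5$significant)
  expect_gt(res5$observed, quantile(res5$null, 0.975))
})

test_that("score correlations match the closed-form Pearson oracle", {
  expect_equal(score_correlation(1:5, 2 * (1:5) + 3)$r, 1)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 5, 4, 5)
  res <- score_correlation(x, y)
  expect_equal(res$r, 6 / sqrt(60), tolerance = 1e-12)   # 0.7745967
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-9)

  expect_error(score_correlation(x, rep(1, 5)), "zero variance")
  expect_error(score_correlation(c(1, 2), c(3, 4)), ">= 3")

  # named alignment
  res2 <- score_correlation(setNames(x, paste0("d", 1:5)),
                            setNames(rev(y), paste0("d", 5:1)))
  expect_equal(res2$r, res$r)
})

test_that("permutation p-values are calibrated under the null", {
  # label-exchangeable null: the selection rate at the 95th percentile
  # threshold is ~5% over replicate null tables
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    df <- null_spectra(6, c("CI", "SI"), 24)
    sel <- suppressWarnings(
      permutation_band_selection(df, n_perm = 99, percentile = 95, seed = s + 1000))
    length(sel$clusters) > 0
  }, logical(1))
  rate <- mean(hits)
  ci <- binom.test(sum(hits), 60, 0.05)$conf.int
  expect_true(0.05 >= ci[1] && 0.05 <= ci[2])
})
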