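# helpers: a constant-coherence map and a tiny preprocessed dyad
const_map <- function(value, n_scales = 10, nt = 400, rate = 10) {
  g <- make_scale_grid(2, 40, n_scales)
  structure(list(values = matrix(value, n_scales, nt), scale_grid = g,
                 sampling_rate = rate, times = (seq_len(nt) - 1) / rate,
                 coi = insync:::coi_periods(nt, rate)),
            class = "coherence_map")
}

small_dyad <- function(seed = 3, duration = 240, strength = 0.8, lag = 5) {
  # 0.02 Hz spectral width: ~8 s temporal correlation, so the injected
  # lag is identifiable from a single dyad
  cfg <- sim_config(n_dyads = 2, n_channels = 2, duration_s = duration,
                    couplings = list(coupling_spec("CH1", "CH2", 0.05, 0.02,
                                                   lag, strength, "SI")),
                    artifacts = artifact_spec(0, 6, 0, 2),
                    strength_jitter_sd = 0, seed = seed)
  list(task = generate_dyad(cfg, "dyad01", "SI"),
       rest = generate_dyad(cfg, "dyad01", "rest"),
       lay_task = insync:::condition_layout("SI", duration),
       lay_rest = make_rest_layout("rest", duration))
}

test_that("channel-wise coherence covers every montage pair", {
  set.seed(8)
  recA <- recording(matrix(rnorm(2 * 400), 2), 10)
  recC <- recording(matrix(rnorm(3 * 400), 3), 10)
  g <- make_scale_grid(2, 20, 8)
  maps <- channelwise_ins(recA, recC, g)
  expect_length(maps, 6)                      # 2 x 3 montage
  expect_named(maps, c("CH1|CH1", "CH2|CH1", "CH1|CH2",
                       "CH2|CH2", "CH1|CH3", "CH2|CH3"))

  # full 26 x 26 montage yields 676 pairs
  a26 <- recording(matrix(rnorm(26 * 64), 26), 10)
  c26 <- recording(matrix(rnorm(26 * 64), 26), 10)
  g0 <- make_scale_grid(0.4, 2, 4)
  expect_length(channelwise_ins(a26, c26, g0), 676)

  # identical inputs: diagonal pairs are perfectly coherent
  same <- channelwise_ins(recA, recording(recA$data, 10), g,
                          pairs = data.frame(chA = c("CH1", "CH2"),
                                             chC = c("CH1", "CH2")))
  for (m in same) expect_lt(max(abs(m$values - 1)), 1e-6)
  expect_error(channelwise_ins(recA, recC, g,
                               pairs = data.frame(chA = "CH9", chC = "CH1")),
               "outside the montage")
})

test_that("task averaging is the Fisher-z mean over task samples", {
  m <- const_map(0.5)
  lay <- make_rest_layout("rest", 40)
  avg <- task_average(m, lay)
  expect_equal(as.numeric(avg), rep(atanh(sqrt(0.5)), 10), tolerance = 1e-12)
  expect_equal(attr(avg, "condition"), "rest")

  # task period = whole record equals the global mean
  set.seed(10)
  vals <- matrix(runif(10 * 400), 10)
  m2 <- const_map(0); m2$values <- vals
  avg2 <- task_average(m2, lay)
  expect_equal(as.numeric(avg2), rowMeans(fisher_z(vals)), tolerance = 1e-12)

  # a window covering part of the record averages only those samples
  lay3 <- session_layout("rest", data.frame(start_s = 10, end_s = 20))
  avg3 <- task_average(m2, lay3)
  sel <- m2$times >= 10 & m2$times < 20
  expect_equal(as.numeric(avg3), rowMeans(fisher_z(vals[, sel])), tolerance = 1e-12)

  out <- session_layout("rest", data.frame(start_s = 50, end_s = 60))
  expect_error(task_average(m2, out), "no samples")
})

test_that("INS increase subtracts the matched rest and only that", {
  m <- const_map(0.6)
  task_ci <- task_average(m, insync:::condition_layout("CI", 40))
  task_si <- task_average(m, insync:::condition_layout("SI", 40))
  rest <- task_average(m, make_rest_layout("rest", 40))
  rain <- task_average(m, make_rest_layout("rest_rain", 40))

  expect_equal(as.numeric(ins_increase(task_ci, rain)), rep(0, 10))
  expect_equal(as.numeric(ins_increase(task_si, rest)), rep(0, 10))
  expect_error(ins_increase(task_ci, rest), "rest_rain")
  expect_error(ins_increase(task_si, rain), "rest")

  # antisymmetry under swapping the two inputs
  m2 <- const_map(0.3)
  rain2 <- task_average(m2, make_rest_layout("rest_rain", 40))
  expect_equal(as.numeric(ins_increase(task_ci, rain2)),
               -as.numeric(ins_increase(rain2, task_ci)), tolerance = 1e-12)

  short <- task_average(const_map(0.5, n_scales = 5), make_rest_layout("rest_rain", 40))
  expect_error(ins_increase(task_ci, short), "differ")
})

test_that("band averaging selects exactly the scales inside the band", {
  g <- make_scale_grid(0.3, 128, 106)
  v <- rnorm(106)
  x <- structure(v, periods = g$periods)

  # the 0.020-0.032 Hz band of interest corresponds to periods 31.25-50 s
  sel <- g$periods >= 31.25 & g$periods <= 50
  expect_equal(band_average(x, c(0.020, 0.032)), mean(v[sel]))
  expect_true(any(sel))

  # invariant to values outside the band
  v2 <- v; v2[!sel] <- v2[!sel] + 100
  expect_equal(band_average(structure(v2, periods = g$periods), c(0.020, 0.032)),
               band_average(x, c(0.020, 0.032)))

  # a band covering a single scale returns that scale's value
  j <- 50
  f <- 1 / g$periods[j]
  expect_equal(band_average(x, c(f - 1e-9, f + 1e-9)), v[j])
  # a band falling strictly between two adjacent scales is empty
  gap <- c(1 / (g$periods[j] * 1.018), 1 / (g$periods[j] * 1.007))
  expect_error(band_average(x, gap), "no scales")
  expect_error(band_average(x, c(0.05, 0.02)), "band")
})

test_that("phase averaging applies the hemodynamic delay to the windows", {
  m <- const_map(0, n_scales = 4, nt = 1000)     # 100 s at 10 Hz
  m$values[] <- rep(seq_len(1000) %% 2, each = 4) # alternating columns
  lay <- session_layout("CI", data.frame(start_s = 0, end_s = 100),
                        data.frame(start_s = c(10, 40), duration_s = 30,
                                   phase_tag = c("A_speak_C_listen",
                                                 "C_speak_A_listen"),
                                   turn_index = 1L))
  ph <- phase_average(m, lay, delay_s = 6)
  # window [16, 46) for the first phase: check against a direct average
  sel <- m$times >= 16 & m$times < 46
  expect_equal(ph$value[ph$phase_tag == "A_speak_C_listen"],
               rep(mean(fisher_z(m$values[1, sel])), 4), tolerance = 1e-12)

  # delay 0 reduces to the plain phase mean
  ph0 <- phase_average(m, lay, delay_s = 0)
  sel0 <- m$times >= 10 & m$times < 40
  expect_equal(ph0$value[ph0$phase_tag == "A_speak_C_listen"],
               rep(mean(fisher_z(m$values[1, sel0])), 4), tolerance = 1e-12)

  # constant map: all phase means equal
  mc <- const_map(0.4, n_scales = 4, nt = 1000)
  phc <- phase_average(mc, lay, delay_s = 6)
  expect_equal(phc$value, rep(atanh(sqrt(0.4)), 8), tolerance = 1e-12)
  pooled <- phase_pool(phc)
  expect_equal(nrow(pooled), 8)                 # 2 tags x 4 scales

  # truncation warning and fully-outside error
  lay_late <- session_layout("CI", data.frame(start_s = 0, end_s = 100),
                             data.frame(start_s = 69, duration_s = 30,
                                        phase_tag = "A_speak_C_listen",
                                        turn_index = 1L))
  expect_warning(phase_average(mc, lay_late, delay_s = 6), "truncated")
  lay_out <- session_layout("CI", data.frame(start_s = 0, end_s = 200),
                            data.frame(start_s = 120, duration_s = 45,
                                       phase_tag = "A_speak_C_listen",
                                       turn_index = 1L))
  expect_error(phase_average(mc, lay_out, delay_s = 6), "outside")
})

test_that("the lag grid and lag-0 identity behave as specified", {
  expect_length(lag_grid(26), 53)
  expect_true(0 %in% lag_grid(26))
  expect_equal(lag_grid(3), -3:3)

  d <- small_dyad()
  g <- make_scale_grid(4, 40, 16)
  pairs <- data.frame(chA = "CH1", chC = "CH2")
  tab0 <- lagged_ins(d$task$A, d$task$C, d$lay_task, d$rest$A, d$rest$C,
                     d$lay_rest, lags_s = 0L, grid = g, pairs = pairs)
  # lag 0 equals the unlagged pipeline bit for bit
  m_task <- channelwise_ins(d$task$A, d$task$C, g, pairs = pairs)[[1]]
  m_rest <- channelwise_ins(d$rest$A, d$rest$C, g, pairs = pairs)[[1]]
  direct <- ins_increase(task_average(m_task, d$lay_task),
                         task_average(m_rest, d$lay_rest))
  expect_identical(tab0$value, as.numeric(direct))

  expect_error(lagged_ins(d$task$A, d$task$C, d$lay_task, d$rest$A, d$rest$C,
                          make_rest_layout("rest_rain", 240),
                          lags_s = 0L, grid = g, pairs = pairs),
               "rest")
})

test_that("swapping participant roles negates the lag axis", {
  d <- small_dyad()
  g <- make_scale_grid(4, 40, 16)
  lags <- c(-6L, 0L, 6L)
  ab <- lagged_ins(d$task$A, d$task$C, d$lay_task, d$rest$A, d$rest$C,
                   d$lay_rest, lags_s = lags, grid = g,
                   pairs = data.frame(chA = "CH1", chC = "CH2"))
  ba <- lagged_ins(d$task$C, d$task$A, d$lay_task, d$rest$C, d$rest$A,
                   d$lay_rest, lags_s = lags, grid = g,
                   pairs = data.frame(chA = "CH2", chC = "CH1"))
  for (lg in lags) {
    x <- ab$value[ab$lag_s == lg]
    y <- ba$value[ba$lag_s == -lg]
    expect_lt(max(abs(x - y)), 1e-9)
  }
})

test_that("a lagged coupling peaks at its injected lag in the INS table", {
  d <- small_dyad(seed = 17, strength = 0.85, lag = 5)
  g <- make_scale_grid(4, 40, 16)
  tab <- lagged_ins(d$task$A, d$task$C, d$lay_task, d$rest$A, d$rest$C,
                    d$lay_rest, lags_s = seq(-1L, 11L, 2L), grid = g,
                    pairs = data.frame(chA = "CH1", chC = "CH2"))
  ba <- band_average_ins(tab, c(0.04, 0.0666))
  expect_lte(abs(ba$lag_s[which.max(ba$value)] - 5), 2)
})

test_that("cohort INS tables are deterministic and coupling-ordered", {
  cfg <- sim_config(n_dyads = 3, n_channels = 1, duration_s = 200,
                    couplings = list(coupling_spec("CH1", "CH1", 0.05, 0.012,
                                                   0, 0.8, "SI")),
                    artifacts = artifact_spec(0.3, 6, 0.05, 2),
                    strength_jitter_sd = 0, seed = 9)
  co <- generate_cohort(cfg)
  g <- make_scale_grid(4, 40, 16)
  t1 <- cohort_ins(co, g, trim_s = 20)
  t2 <- cohort_ins(co, g, trim_s = 20)
  expect_identical(t1, t2)
  ba <- band_average_ins(t1, c(0.04, 0.0666))
  means <- tapply(ba$value, ba$condition, mean)
  expect_gt(means[["SI"]], means[["CI"]])

  # rest-free cohort cannot be baselined
  co$recordings <- lapply(co$recordings, function(d) d[c("CI", "SI", "rest")])
  expect_error(cohort_ins(co, g, trim_s = 20), "rain")

  # coupling-free rests: INS increase centred on zero
  cfg0 <- sim_config(n_dyads = 20, n_channels = 1, duration_s = 150,
                     couplings = list(), artifacts = artifact_spec(0, 6, 0, 2),
                     seed = 101)
  co0 <- generate_cohort(cfg0, conditions = "SI")
  tb <- cohort_ins(co0, g, trim_s = 20, tddr_par = NULL)
  per_dyad <- tapply(tb$value, tb$dyad, mean)
  expect_lt(abs(mean(per_dyad)), 2 * sd(per_dyad) / sqrt(length(per_dyad)))
})
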