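#' Pipeline configuration
#'
#' A single serialisable object describing an end-to-end run: simulation
#' (or paths to recordings on disk), wavelet and lag settings,
#' band-selection and test parameters, a global seed and an output
#' directory.  Every run is reproducible from `(config, seed)` alone; a
#' JSON snapshot of the configuration is written beside the outputs.
#'
#' `demo_config()` returns a small configuration (reduced montage, short
#' recordings) that exercises every stage in well under a minute per
#' stage.
#'
#' @param sim list of arguments for [sim_config()], or an already-built
#'   `sim_config`.
#' @param conditions task conditions to simulate and contrast (first two
#'   are contrasted in the group test).
#' @param grid list `list(min_scale=, max_scale=, n_scales=)`.
#' @param omega0 Morlet centre frequency.
#' @param max_lag_s,lag_step_s lag grid for the lagged scan.
#' @param pairs `"coupled"` (only pairs named in the couplings, fast),
#'   `"all"`, or a data frame (chA, chC).
#' @param band `NULL` to select bands by permutation, or a fixed
#'   `c(f_lo, f_hi)` Hz.
#' @param band_n_perm,band_percentile,merge_gap band-selection settings.
#' @param alpha family-wise level for the Bonferroni-corrected paired
#'   tests.
#' @param validation_n_perm,validation_area pseudo-dyad validation
#'   settings.
#' @param delay_s hemodynamic delay for phase averaging.
#' @param trim_s edge trim seconds.
#' @param seed global seed; stage seeds are derived from it.
#' @param out_dir output directory, or `NULL` to keep results in memory
#'   only.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), conditions = c("CI", "SI"),
                            grid = list(min_scale = 0.3, max_scale = 128,
                                        n_scales = 106),
                            omega0 = 6, max_lag_s = 26, lag_step_s = 1,
                            pairs = "coupled", band = NULL,
                            band_n_perm = 1000, band_percentile = 99,
                            merge_gap = 2, alpha = 0.05,
                            validation_n_perm = 1000, validation_area = 0.05,
                            delay_s = 6, trim_s = 30, seed = 1,
                            out_dir = NULL) {
  cfg <- list(sim = sim, conditions = conditions, grid = grid,
              omega0 = omega0, max_lag_s = max_lag_s, lag_step_s = lag_step_s,
              pairs = pairs, band = band, band_n_perm = band_n_perm,
              band_percentile = band_percentile, merge_gap = merge_gap,
              alpha = alpha, validation_n_perm = validation_n_perm,
              validation_area = validation_area, delay_s = delay_s,
              trim_s = trim_s, seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param n_dyads,duration_s,seed demo-size overrides.
#' @export
demo_config <- function(n_dyads = 10, duration_s = 300, seed = 42,
                        out_dir = NULL) {
  couplings <- list(
    coupling_spec("CH1", "CH2", 0.025, 0.010, 17, 0.7, "SI"),
    coupling_spec("CH1", "CH2", 0.025, 0.010, 17, 0.1, "CI"),
    coupling_spec("CH2", "CH1", 0.065, 0.015, 0, 0.7, "CI"),
    coupling_spec("CH2", "CH1", 0.065, 0.015, 0, 0.1, "SI")
  )
  pipeline_config(
    sim = list(n_dyads = n_dyads, n_channels = 2, duration_s = duration_s,
               couplings = couplings, artifacts = artifact_spec(0.3, 6, 0.05, 2)),
    grid = list(min_scale = 2, max_scale = 80, n_scales = 48),
    max_lag_s = 26, lag_step_s = 1,
    band_n_perm = 200, validation_n_perm = 200,
    seed = seed, out_dir = out_dir)
}

#' Read or write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$sim$couplings) && is.data.frame(obj$sim$couplings)) {
    obj$sim$couplings <- lapply(seq_len(nrow(obj$sim$couplings)), function(i) {
      r <- obj$sim$couplings[i, ]
      coupling_spec(r$chA, r$chC, r$center_freq, r$bandwidth, r$lag_s,
                    r$strength, r$conditions[[1]])
    })
  }
  if (!is.null(obj$sim$noise)) obj$sim$noise <- do.call(noise_spec, obj$sim$noise)
  if (!is.null(obj$sim$artifacts)) {
    obj$sim$artifacts <- do.call(artifact_spec, obj$sim$artifacts)
  }
  if (!is.null(obj$sim$duration_s)) obj$sim$duration_s <- unlist(obj$sim$duration_s)
  do.call(pipeline_config, obj[setdiff(names(obj), character(0))])
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  if (length(cfg$sim) && !is.null(cfg$sim$couplings)) {
    cfg$sim$couplings <- do.call(rbind, lapply(cfg$sim$couplings, function(cp) {
      data.frame(chA = cp$chA, chC = cp$chC, center_freq = cp$center_freq,
                 bandwidth = cp$bandwidth, lag_s = cp$lag_s,
                 strength = cp$strength,
                 conditions = I(list(cp$conditions)))
    }))
  }
  jsonlite::write_json(strip_s3(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Drop S3 classes from nested spec objects so they serialise as plain
# JSON objects (data frames are kept as such).
strip_s3 <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_s3))
  x
}

#' Synthetic behavioural scores from simulation ground truth
#'
#' Maps each dyad's realized coupling strength (averaged over the truth
#' rows of the given channel pair) to an interpretation-style score on
#' a 0-10 scale plus Gaussian noise, so that the score-INS correlation
#' stage has a meaningful target in simulated cohorts.
#'
#' @param cohort an `ins_cohort` with ground truth.
#' @param target_pair `c(chA, chC)`; defaults to the first coupling.
#' @param noise_sd score noise standard deviation.
#' @param seed integer seed.
#' @return data frame (dyad, reverse_score, forward_score).
#' @export
synthesize_scores <- function(cohort, target_pair = NULL, noise_sd = 0.5,
                              seed = 1) {
  tr <- cohort$truth
  if (is.null(tr) || !nrow(tr)) stopf("cohort has no coupling ground truth")
  if (is.null(target_pair)) target_pair <- c(tr$chA[1], tr$chC[1])
  sub <- tr[tr$chA == target_pair[1] & tr$chC == target_pair[2], ]
  if (!nrow(sub)) stopf("no truth rows for pair %s-%s", target_pair[1], target_pair[2])
  st <- tapply(sub$strength, sub$dyad, mean)
  with_seed(seed, {
    base <- 6 + 3 * (st - mean(st)) / max(sd(st), 1e-12)
    data.frame(dyad = names(st),
               reverse_score = as.numeric(base + rnorm(length(st), 0, noise_sd)),
               forward_score = as.numeric(base + rnorm(length(st), 0, noise_sd)))
  })
}

run_stage <- function(name, quiet, expr) {
  t0 <- proc.time()[3]
  res <- tryCatch(force(expr), error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
  if (!quiet) message(sprintf("[%s] done in %.1f s", name, proc.time()[3] - t0))
  res
}

#' Run the full INS analysis pipeline
#'
#' Executes simulate -> preprocess/INS -> band selection -> lagged group
#' test -> pseudo-dyad validation -> score correlations on a simulated
#' cohort, writing all intermediate tables to `config$out_dir` (if set)
#' and returning the result bundle.
#'
#' @param config a [pipeline_config()].
#' @param scores optional data frame (dyad, reverse_score,
#'   forward_score); synthesised from ground truth when omitted.
#' @param quiet suppress per-stage progress messages.
#' @return list of class `ins_pipeline_result` with elements `cohort`,
#'   `ins` (lag-0 table), `bands`, `band`, `lagged`, `group_test`,
#'   `validation`, `correlations`, `config`.
#' @export
run_pipeline <- function(config, scores = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, fname, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, fname))
    obj
  }
  emit(config, "config.json", write_pipeline_config)

  sim <- config$sim
  if (!inherits(sim, "sim_config")) {
    sim$seed <- child_seed(config$seed, "sim")
    sim <- do.call(sim_config, sim)
  }
  cohort <- run_stage("simulate", quiet, generate_cohort(sim, config$conditions))

  grid <- make_scale_grid(config$grid$min_scale, config$grid$max_scale,
                          config$grid$n_scales, morlet_params(config$omega0))
  pairs <- resolve_pairs(config$pairs, sim)

  ins0 <- run_stage("ins", quiet,
    cohort_ins(cohort, grid, pairs = pairs, lags_s = 0L,
               trim_s = config$trim_s))
  emit(ins0, "ins_lag0.tsv", write_ins_table)

  band_sel <- NULL
  band <- config$band
  if (is.null(band)) {
    spectra <- run_stage("select-bands", quiet, {
      agg <- stats::aggregate(value ~ dyad + condition + scale_index + period_s,
                              data = ins0, FUN = mean)
      permutation_band_selection(agg, n_perm = config$band_n_perm,
                                 percentile = config$band_percentile,
                                 seed = child_seed(config$seed, "bands"),
                                 merge_gap = config$merge_gap)
    })
    band_sel <- spectra
    if (!is.null(band_sel$merged_bands) && nrow(band_sel$merged_bands)) {
      b <- band_sel$merged_bands[which.max(
        band_sel$merged_bands$scale_hi - band_sel$merged_bands$scale_lo), ]
      band <- c(b$f_lo, b$f_hi)
    } else {
      warnf("no band selected by permutation; falling back to 0.02-0.08 Hz")
      band <- c(0.02, 0.08)
    }
    if (!is.null(out_dir)) {
      jsonlite::write_json(list(band = band,
                                merged_bands = band_sel$merged_bands,
                                threshold = band_sel$threshold),
                           file.path(out_dir, "bands.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }

  lagged <- run_stage("lagged-ins", quiet,
    cohort_ins(cohort, grid, pairs = pairs,
               lags_s = lag_grid(config$max_lag_s, config$lag_step_s),
               trim_s = config$trim_s))
  emit(lagged, "ins_lagged.tsv", write_ins_table)

  gt <- run_stage("group-test", quiet, {
    ba <- band_average_ins(lagged, band)
    a <- ba[ba$condition == config$conditions[1], ]
    b <- ba[ba$condition == config$conditions[2], ]
    paired_condition_test(a, b, alpha = config$alpha)
  })
  if (!is.null(out_dir)) {
    write.table(gt, file.path(out_dir, "group_test.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  top <- gt[1, ]
  validation <- run_stage("validate", quiet,
    pseudo_pair_permutation(cohort,
                            target_pair = c(top$chA, top$chC),
                            target_lag_s = top$lag_s, band = band,
                            conditions = config$conditions,
                            n_perm = config$validation_n_perm,
                            seed = child_seed(config$seed, "validate"),
                            two_tailed_area = config$validation_area,
                            grid = grid, trim_s = config$trim_s))
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(observed = validation$observed,
                              p_two_tailed = validation$p_two_tailed,
                              significant = validation$significant,
                              method = validation$method),
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  correlations <- NULL
  if ("CI" %in% config$conditions && !is.null(cohort$truth)) {
    correlations <- run_stage("correlate", quiet, {
      if (is.null(scores)) {
        scores <- synthesize_scores(cohort, c(top$chA, top$chC),
                                    seed = child_seed(config$seed, "scores"))
      }
      ph <- phase_ins_by_dyad(cohort, c(top$chA, top$chC), band, grid,
                              config$delay_s, config$trim_s)
      list(first_phase = score_correlation(ph$A_speak_C_listen,
             setNames(scores$reverse_score, scores$dyad)),
           second_phase = score_correlation(ph$C_speak_A_listen,
             setNames(scores$forward_score, scores$dyad)),
           scores = scores, phase_ins = ph)
    })
    if (!is.null(out_dir)) {
      jsonlite::write_json(list(
        first_phase = correlations$first_phase[c("r", "p", "n")],
        second_phase = correlations$second_phase[c("r", "p", "n")]),
        file.path(out_dir, "correlations.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  structure(list(cohort = cohort, ins = ins0, bands = band_sel, band = band,
                 lagged = lagged, group_test = gt, validation = validation,
                 correlations = correlations, config = config),
            class = "ins_pipeline_result")
}

# Per-dyad, per-phase-type band-averaged INS increase at one channel
# pair in the CI condition (phase windows shifted by the hemodynamic
# delay; baseline: matched rest spectrum).
phase_ins_by_dyad <- function(cohort, target_pair, band, grid, delay_s,
                              trim_s) {
  pairs <- data.frame(chA = target_pair[1], chC = target_pair[2])
  out <- list(A_speak_C_listen = c(), C_speak_A_listen = c())
  for (d in names(cohort$recordings)) {
    A <- preprocess_recording(cohort$recordings[[d]]$CI$A, trim_s)
    C <- preprocess_recording(cohort$recordings[[d]]$CI$C, trim_s)
    lay <- shift_layout(cohort$layouts$CI, -trim_s, duration_s(A))
    map <- channelwise_ins(A, C, grid, pairs = pairs)[[1]]
    ph <- phase_pool(phase_average(map, lay, delay_s))
    rA <- preprocess_recording(cohort$recordings[[d]]$rest_rain$A, trim_s)
    rC <- preprocess_recording(cohort$recordings[[d]]$rest_rain$C, trim_s)
    lay_r <- shift_layout(cohort$layouts$rest_rain, -trim_s, duration_s(rA))
    rest_map <- channelwise_ins(rA, rC, grid, pairs = pairs)[[1]]
    rest_band <- band_average(task_average(rest_map, lay_r), band)
    for (tag in names(out)) {
      sub <- ph[ph$phase_tag == tag, ]
      val <- band_average(sub$value, band, periods = sub$period_s) - rest_band
      out[[tag]][d] <- val
    }
  }
  out
}

# "coupled": only the channel pairs named in the couplings; "all": full
# montage cross; a data frame passes through.
resolve_pairs <- function(pairs, sim) {
  if (is.data.frame(pairs)) return(pairs)
  if (identical(pairs, "all")) return(NULL)
  if (identical(pairs, "coupled")) {
    if (!length(sim$couplings)) stopf("no couplings to derive pairs from")
    df <- unique(do.call(rbind, lapply(sim$couplings, function(cp) {
      data.frame(chA = cp$chA, chC = cp$chC)
    })))
    rownames(df) <- NULL
    return(df)
  }
  stopf("pairs must be 'coupled', 'all', or a data frame (chA, chC)")
}

#' @rdname run_pipeline
#' @param x an `ins_pipeline_result`.
#' @param ... ignored.
#' @export
print.ins_pipeline_result <- function(x, ...) {
  cat("<ins_pipeline_result>\n")
  cat(sprintf("  band: %.3f-%.3f Hz\n", x$band[1], x$band[2]))
  nsig <- sum(x$group_test$significant)
  cat(sprintf("  group test: %d significant (pair, lag) cells of %d (m = %d)\n",
              nsig, nrow(x$group_test), attr(x$group_test, "m")))
  top <- x$group_test[1, ]
  cat(sprintf("  top cell: %s-%s at lag %d s (t = %.2f, p_bonf = %.3g)\n",
              top$chA, top$chC, top$lag_s, top$t, top$p_bonf))
  cat(sprintf("  validation: observed %.3f, two-tailed p = %.3g (%s)\n",
              x$validation$observed, x$validation$p_two_tailed,
              x$validation$method))
  if (!is.null(x$correlations)) {
    cat(sprintf("  correlations: first phase r = %.3f (p = %.3g), second r = %.3f (p = %.3g)\n",
                x$correlations$first_phase$r, x$correlations$first_phase$p,
                x$correlations$second_phase$r, x$correlations$second_phase$p))
  }
  invisible(x)
}
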