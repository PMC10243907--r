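#' Single-participant fNIRS recording
#'
#' An `ins_recording` holds one participant's multichannel oxygenated
#' hemoglobin (HbO) time series: a channels-by-samples numeric matrix, the
#' sampling rate in Hz, an ordered set of channel labels, and optionally a
#' map from channels to anatomical region tags (e.g. `CH15 -> lTPJ`).
#'
#' @param data numeric matrix, channels x samples.  A plain vector is
#'   treated as a single channel.
#' @param sampling_rate samples per second (Hz), positive.
#' @param participant_role role label for hyperscanning bookkeeping,
#'   conventionally `"A"` or `"C"` for the two interlocutors.
#' @param channel_labels character vector, one label per row of `data`.
#'   Defaults to `CH1 ... CHn`.
#' @param region_labels optional named character vector mapping channel
#'   labels to region tags.
#' @return An object of class `ins_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(200), nrow = 2), sampling_rate = 10)
#' n_channels(rec)
#' duration_s(rec)
#' @export
recording <- function(data, sampling_rate, participant_role = "A",
                      channel_labels = NULL, region_labels = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric channels x samples matrix")
  }
  if (anyNA(data) || !all(is.finite(data))) {
    stopf("recording data contain missing or non-finite values")
  }
  if (!is_scalar_num(sampling_rate) || sampling_rate <= 0) {
    stopf("`sampling_rate` must be a positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("CH", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stopf("%d channel labels for %d channels", length(channel_labels), nrow(data))
  }
  rownames(data) <- channel_labels
  if (!is.null(region_labels)) {
    unknown <- setdiff(names(region_labels), channel_labels)
    if (length(unknown)) {
      stopf("region labels refer to unknown channels: %s",
            paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(participant_role = participant_role,
         sampling_rate = as.numeric(sampling_rate),
         data = data,
         channel_labels = as.character(channel_labels),
         region_labels = region_labels),
    class = "ins_recording"
  )
}

#' @rdname recording
#' @param x,rec an `ins_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$sampling_rate

#' @rdname recording
#' @param ... ignored.
#' @export
print.ins_recording <- function(x, ...) {
  cat(sprintf("<ins_recording> role %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$participant_role, n_channels(x), n_samples(x),
              x$sampling_rate, duration_s(x)))
  invisible(x)
}

#' Read and write recordings as TSV plus JSON sidecar
#'
#' The native on-disk format is a tab-separated table whose first column is
#' `time_s` (seconds from recording start, uniform steps) and remaining
#' columns are channels, plus a JSON sidecar `<path>.json` carrying the
#' participant role, sampling rate, channel labels, and optional region
#' labels.  Readers validate rather than repair: non-uniform time steps
#' (beyond 1e-6 s), missing cells, or a sidecar rate that contradicts the
#' time column are errors.
#'
#' @param path file path of the TSV table.  The sidecar lives at
#'   `<path>.json`.
#' @param format_hint only `"tsv"` is supported; `"snirf"` raises an
#'   informative error (no HDF5 reader is bundled).
#' @return `read_recording()` returns an [recording()] object;
#'   `write_recording()` invisibly returns `path`.
#' @export
read_recording <- function(path, format_hint = "tsv") {
  if (!identical(format_hint, "tsv")) {
    stopf("unsupported format_hint '%s': only the native TSV + sidecar format is supported",
          format_hint)
  }
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- read.delim(path, check.names = FALSE)
  if (ncol(tab) < 2L || names(tab)[1] != "time_s") {
    stopf("malformed recording table: first column must be 'time_s'")
  }
  if (anyNA(tab)) stopf("malformed recording table: missing cells")
  tt <- tab[["time_s"]]
  if (length(tt) < 2L) stopf("recording must have at least 2 samples")
  steps <- diff(tt)
  if (max(steps) - min(steps) > 1e-6 || any(steps <= 0)) {
    stopf("malformed recording table: non-uniform time step")
  }
  dt <- mean(steps)
  rate <- 1 / dt
  side_path <- paste0(path, ".json")
  role <- "A"; regions <- NULL
  labels <- names(tab)[-1]
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$sampling_rate) &&
        abs(side$sampling_rate - rate) > 1e-6 * rate) {
      stopf("sidecar sampling rate %g Hz contradicts time column (%g Hz)",
            side$sampling_rate, rate)
    }
    if (!is.null(side$participant_role)) role <- side$participant_role
    if (!is.null(side$channel_labels)) {
      if (!identical(as.character(side$channel_labels), labels)) {
        stopf("sidecar channel labels disagree with table header")
      }
    }
    if (!is.null(side$region_labels) && length(side$region_labels)) {
      regions <- unlist(side$region_labels)
    }
  }
  data <- t(as.matrix(tab[-1]))
  recording(data, sampling_rate = rate, participant_role = role,
            channel_labels = labels, region_labels = regions)
}

#' @rdname read_recording
#' @param rec an `ins_recording` to write.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ins_recording"))
  tt <- (seq_len(n_samples(rec)) - 1L) / rec$sampling_rate
  tab <- data.frame(time_s = tt, t(rec$data), check.names = FALSE)
  write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(participant_role = rec$participant_role,
               sampling_rate = rec$sampling_rate,
               channel_labels = rec$channel_labels)
  if (!is.null(rec$region_labels)) side$region_labels <- as.list(rec$region_labels)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Channel-to-region lookup for the standard 26-channel montage
#'
#' Static table mapping the 22-channel left fronto-temporo-parietal probe
#' patch plus the 4-channel right temporoparietal patch to region tags.
#' Anatomical labelling itself (MNI projection, Brodmann assignment) is out
#' of scope; this fixture records the channels the downstream statistics
#' refer to, notably `CH15 = lTPJ`, `CH24 = rTPJ`, and `CH17`/`CH8 = lIFG`.
#'
#' @return named character vector of length 26 (names `CH1...CH26`).
#' @export
channel_regions <- function() {
  path <- system.file("extdata", "channel_regions.tsv", package = "insync",
                      mustWork = TRUE)
  tab <- read.delim(path)
  setNames(tab$region, tab$channel)
}
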