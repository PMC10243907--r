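#' Session layout: conditions, blocks, and turn-taking phases
#'
#' A `session_layout` describes the timeline of one recording session:
#' the condition (`CI` consecutive interpreting, `SI` simultaneous
#' interpreting, `CC` mother-tongue retelling, `rest`, or `rest_rain`),
#' the task blocks as `[start_s, end_s]` intervals, and the turn-taking
#' phases inside the blocks.  Each phase is a half-open window
#' `[start_s, start_s + duration_s)` tagged `A_speak_C_listen` or
#' `C_speak_A_listen`.  Times are seconds from recording start.
#'
#' Validation is strict: phases must be sorted, non-overlapping,
#' contiguous within a block, and contained in their block.
#'
#' @param condition one of `"CI"`, `"SI"`, `"CC"`, `"rest"`, `"rest_rain"`.
#' @param blocks data frame with columns `start_s`, `end_s`.
#' @param turns data frame with columns `start_s`, `duration_s`,
#'   `phase_tag`, `turn_index`; may have zero rows (rest conditions).
#' @return An object of class `ins_layout`.
#' @export
session_layout <- function(condition, blocks, turns = NULL) {
  conds <- c("CI", "SI", "CC", "rest", "rest_rain")
  if (!condition %in% conds) {
    stopf("unknown condition '%s' (expected one of %s)", condition,
          paste(conds, collapse = ", "))
  }
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("start_s", "end_s") %in% names(blocks)))
  if (nrow(blocks)) {
    if (any(blocks$end_s <= blocks$start_s)) stopf("block with non-positive length")
    o <- order(blocks$start_s)
    blocks <- blocks[o, , drop = FALSE]
    if (nrow(blocks) > 1L &&
        any(blocks$start_s[-1] < blocks$end_s[-nrow(blocks)])) {
      stopf("overlapping blocks")
    }
  }
  if (is.null(turns)) {
    turns <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                        phase_tag = character(0), turn_index = integer(0))
  }
  turns <- as.data.frame(turns)
  stopifnot(all(c("start_s", "duration_s", "phase_tag", "turn_index") %in% names(turns)))
  if (nrow(turns)) {
    tags <- c("A_speak_C_listen", "C_speak_A_listen")
    if (!all(turns$phase_tag %in% tags)) stopf("unknown phase tag")
    if (any(turns$duration_s <= 0)) stopf("phase with non-positive duration")
    turns <- turns[order(turns$start_s), , drop = FALSE]
    rownames(turns) <- NULL
    ends <- turns$start_s + turns$duration_s
    if (any(turns$start_s[-1] < ends[-nrow(turns)] - 1e-9)) {
      stopf("overlapping phases")
    }
    # every phase must sit inside a block, and phases within a block must
    # be contiguous (no dead time between turns)
    blk <- vapply(seq_len(nrow(turns)), function(i) {
      hit <- which(blocks$start_s - 1e-9 <= turns$start_s[i] &
                   ends[i] <= blocks$end_s + 1e-9)
      if (!length(hit)) {
        inb <- which(blocks$start_s - 1e-9 <= turns$start_s[i] &
                     turns$start_s[i] < blocks$end_s)
        if (length(inb)) stopf("phase extends past block end")
        stopf("phase outside any block")
      }
      hit[1]
    }, integer(1))
    for (b in unique(blk)) {
      idx <- which(blk == b)
      if (length(idx) > 1L) {
        gaps <- turns$start_s[idx[-1]] - ends[idx[-length(idx)]]
        if (any(abs(gaps) > 1e-6)) stopf("phases within a block must be contiguous")
      }
    }
  }
  structure(list(condition = condition, blocks = blocks, turns = turns),
            class = "ins_layout")
}

#' @rdname session_layout
#' @param x an `ins_layout`.
#' @param ... ignored.
#' @export
print.ins_layout <- function(x, ...) {
  cat(sprintf("<ins_layout> %s: %d block(s), %d phase(s)\n",
              x$condition, nrow(x$blocks), nrow(x$turns)))
  invisible(x)
}

#' Standard layouts for the turn-taking paradigm
#'
#' `make_ci_layout()` builds the consecutive-interpreting timeline: blocks
#' open with a fixation period, then turn-takings in which the
#' speaker/listener roles swap every `phase_s` seconds (default 45 s, five
#' turn-takings per block).  `make_si_layout()` builds the simultaneous
#' variant (default eight turn-takings of two 20 s phases).
#' `make_rest_layout()` is a single task-free block (default 5 min).
#'
#' @param n_blocks number of task blocks.
#' @param turns_per_block turn-takings per block (each contributes two
#'   phases: A speaks / C speaks).
#' @param phase_s phase duration in seconds.
#' @param fixation_s fixation period at the top of each block.
#' @param inter_block_s gap between blocks.
#' @return An [session_layout()] object.
#' @export
make_ci_layout <- function(n_blocks = 2, turns_per_block = 5, phase_s = 45,
                           fixation_s = 30, inter_block_s = 30) {
  build_turn_layout("CI", n_blocks, turns_per_block, phase_s, fixation_s,
                    inter_block_s)
}

#' @rdname make_ci_layout
#' @export
make_si_layout <- function(n_blocks = 2, turns_per_block = 8, phase_s = 20,
                           fixation_s = 30, inter_block_s = 30) {
  build_turn_layout("SI", n_blocks, turns_per_block, phase_s, fixation_s,
                    inter_block_s)
}

#' @rdname make_ci_layout
#' @param condition rest flavour: `"rest"` or `"rest_rain"`.
#' @param duration_s rest duration in seconds.
#' @export
make_rest_layout <- function(condition = "rest", duration_s = 300) {
  session_layout(condition,
                 blocks = data.frame(start_s = 0, end_s = duration_s))
}

#' @rdname make_ci_layout
#' @export
make_cc_layout <- function(n_blocks = 2, turns_per_block = 8, phase_s = 20,
                           fixation_s = 30, inter_block_s = 30) {
  build_turn_layout("CC", n_blocks, turns_per_block, phase_s, fixation_s,
                    inter_block_s)
}

build_turn_layout <- function(condition, n_blocks, turns_per_block, phase_s,
                              fixation_s, inter_block_s) {
  block_len <- fixation_s + turns_per_block * 2 * phase_s
  blocks <- data.frame(
    start_s = (seq_len(n_blocks) - 1L) * (block_len + inter_block_s),
    end_s   = (seq_len(n_blocks) - 1L) * (block_len + inter_block_s) + block_len
  )
  rows <- list()
  turn <- 0L
  for (b in seq_len(n_blocks)) {
    t0 <- blocks$start_s[b] + fixation_s
    for (k in seq_len(turns_per_block)) {
      turn <- turn + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = t0 + (k - 1) * 2 * phase_s + c(0, phase_s),
        duration_s = phase_s,
        phase_tag = c("A_speak_C_listen", "C_speak_A_listen"),
        turn_index = turn
      )
    }
  }
  session_layout(condition, blocks, do.call(rbind, rows))
}

#' Read or write a session layout as JSON
#'
#' @param path file path.
#' @return `read_layout()` returns a validated [session_layout()];
#'   phases are sorted by start time.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  turns <- obj$turns
  # zero-length turn columns come back as empty lists
  if (is.null(turns) || length(turns) == 0L ||
      (is.data.frame(turns) && !nrow(turns)) ||
      (is.list(turns) && all(lengths(turns) == 0L))) {
    turns <- NULL
  }
  session_layout(obj$condition, obj$blocks, turns)
}

#' @rdname read_layout
#' @param layout an `ins_layout` to write.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "ins_layout"))
  jsonlite::write_json(unclass(layout), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Re-reference a layout in time
#'
#' Shifts all block and phase times by `offset_s` (negative when leading
#' samples were trimmed) and optionally clips to `[0, clip_to_s]`,
#' dropping blocks and phases that fall entirely outside and truncating
#' those that straddle an edge.
#'
#' @param layout an `ins_layout`.
#' @param offset_s seconds to add to every timestamp.
#' @param clip_to_s optional new recording duration to clip against.
#' @return a re-referenced `ins_layout`.
#' @export
shift_layout <- function(layout, offset_s, clip_to_s = NULL) {
  blocks <- layout$blocks
  blocks$start_s <- blocks$start_s + offset_s
  blocks$end_s <- blocks$end_s + offset_s
  turns <- layout$turns
  if (nrow(turns)) turns$start_s <- turns$start_s + offset_s
  if (!is.null(clip_to_s)) {
    blocks$start_s <- pmax(blocks$start_s, 0)
    blocks$end_s <- pmin(blocks$end_s, clip_to_s)
    blocks <- blocks[blocks$end_s > blocks$start_s, , drop = FALSE]
    if (nrow(turns)) {
      ends <- pmin(turns$start_s + turns$duration_s, clip_to_s)
      turns$start_s <- pmax(turns$start_s, 0)
      turns$duration_s <- ends - turns$start_s
      turns <- turns[turns$duration_s > 0, , drop = FALSE]
    }
  }
  out <- layout
  out$blocks <- blocks
  out$turns <- turns
  out
}
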