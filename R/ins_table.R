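#' INS result tables
#'
#' An INS table is a long-format data frame with one Fisher-z INS-increase
#' value (task minus matched rest) per key
#' `(dyad, condition, chA, chC, scale_index, lag_s)`, plus the scale's
#' period in seconds.  `ins_table()` validates a data frame against that
#' contract; `write_ins_table()`/`read_ins_table()` round-trip it through
#' a TSV file losslessly (to 1e-12).
#'
#' @param df data frame with columns `dyad`, `condition`, `chA`, `chC`,
#'   `scale_index`, `period_s`, `lag_s`, `value`.
#' @param max_lag_s largest admissible |lag| in seconds (default 26).
#' @return a validated data frame of class `ins_table`.
#' @export
ins_table <- function(df, max_lag_s = 26) {
  need <- c("dyad", "condition", "chA", "chC", "scale_index", "period_s",
            "lag_s", "value")
  df <- as.data.frame(df)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("ins_table missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (any(abs(df$lag_s - round(df$lag_s)) > 1e-9)) {
    stopf("lag_s must be integer seconds")
  }
  if (any(abs(df$lag_s) > max_lag_s)) {
    stopf("lag_s outside [-%g, %g]", max_lag_s, max_lag_s)
  }
  key <- do.call(paste, c(df[c("dyad", "condition", "chA", "chC",
                               "scale_index", "lag_s")], sep = "\r"))
  if (anyDuplicated(key)) stopf("duplicate (dyad, condition, pair, scale, lag) keys")
  class(df) <- c("ins_table", "data.frame")
  df
}

#' @rdname ins_table
#' @param table an `ins_table`.
#' @param path file path of the TSV.
#' @export
write_ins_table <- function(table, path) {
  table <- ins_table(table)
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ins_table
#' @export
read_ins_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c(dyad = "character", condition = "character",
                                  chA = "character", chC = "character"))
  ins_table(df)
}
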