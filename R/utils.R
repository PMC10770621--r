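# Shared table plumbing: tab-separated, UTF-8, '#' comment lines skipped,
# matching STRING/SIGNOR export conventions. Identifiers are opaque,
# case-sensitive symbols; no mapping is ever attempted.

read_tsv_table <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() unless all values are finite numbers within [lo, hi]
check_range <- function(x, lo, hi, what, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(what, " must be finite and non-missing", call. = FALSE)
  }
  bad <- if (lo_open) x <= lo else x < lo
  bad <- bad | if (hi_open) x >= hi else x > hi
  if (any(bad)) {
    stop(what, " outside ", if (lo_open) "(" else "[", lo, ", ", hi,
         if (hi_open) ")" else "]", ": ",
         paste(utils::head(x[bad], 5), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
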