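# Internal helpers shared across modules.

# Signal a classed error so callers can dispatch on condition class.
oe_error <- function(class, message, data = list()) {
  cond <- structure(
    class = c(class, "ontoexpress_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1L)), data)
  )
  stop(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  as.character(x)
}

.check_columns <- function(df, expected, what, exact_order = FALSE) {
  if (exact_order) {
    if (!identical(names(df), expected)) {
      oe_error("oe_schema_mismatch",
               sprintf("%s: expected columns [%s], found [%s]",
                       what, paste(expected, collapse = ", "),
                       paste(names(df), collapse = ", ")))
    }
  } else if (!all(expected %in% names(df))) {
    oe_error("oe_schema_mismatch",
             sprintf("%s: missing columns: %s", what,
                     paste(setdiff(expected, names(df)), collapse = ", ")))
  }
  invisible(df)
}

# Fixed-precision numeric formatting so written files are diffable across runs.
.fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}
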