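# Schema validation for interchange tables: errors name the offending
# column (and first offending row for bad values).
validate_table <- function(df, what, req, numeric_cols = character()) {
  if (!is.data.frame(df)) {
    abort(sprintf("%s must be a data frame", what), "eproximetry_validation")
  }
  if (nrow(df) == 0L) {
    abort(sprintf("%s table is empty", what), "eproximetry_validation")
  }
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    abort(sprintf("%s table lacks column(s): %s", what,
                  paste(miss, collapse = ", ")),
          "eproximetry_validation")
  }
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      abort(sprintf("%s column `%s` must be numeric", what, col),
            "eproximetry_validation")
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(sprintf("%s column `%s` has a non-finite value at row %d",
                    what, col, bad[1L]),
            "eproximetry_validation")
    }
  }
  invisible(df)
}
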