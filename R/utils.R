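#' Path to a built-in data file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @keywords internal
pddialert_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pddialert", mustWork = FALSE)
  if (!nzchar(path)) {
    abort(sprintf("built-in data file '%s' not found", file), class = "pddialert_data_error")
  }
  path
}

# coerce to Date, erroring with a field name on failure
as_date_strict <- function(x, field) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(sprintf("field '%s' contains non ISO-8601 dates (e.g. '%s')",
                  field, as.character(x[which(bad)[1]])),
          class = "pddialert_schema_error")
  }
  out
}

# %||% for defaulting
`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "pddialert_schema_error")
  }
  invisible(df)
}
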