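#' Tabular samples-by-variables dataset
#'
#' Validates and tags a data frame as the unit all discovery algorithms
#' consume: rows are samples, columns are variables, one column is the
#' phenotype. Discrete columns are factors with stable level sets;
#' continuous columns are numeric. Missing values are rejected outright —
#' no algorithm here defines missing-value semantics.
#'
#' @param df a data frame.
#' @param target phenotype column name; must be present.
#' @param kinds optional named character vector (`"discrete"` or
#'   `"continuous"`) declaring column kinds; unnamed columns keep their
#'   current class.
#' @return `df` with factor/numeric columns as declared, a `"target"`
#'   attribute, and class `c("tabular_dataset", "data.frame")`.
#' @export
tabular_dataset <- function(df, target, kinds = NULL) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(names(df))) stop("duplicate column names in dataset")
  if (!target %in% names(df))
    stop("dataset has no target column '", target, "'")
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), names(df))
    if (length(bad)) stop("kind declared for unknown column(s): ",
                          paste(bad, collapse = ", "))
    for (v in names(kinds)) {
      df[[v]] <- switch(kinds[[v]],
        discrete = if (is.factor(df[[v]])) df[[v]] else
          factor(as.character(df[[v]]), levels = sort(unique(as.character(df[[v]])))),
        continuous = as.numeric(df[[v]]),
        stop("unknown kind '", kinds[[v]], "' for column '", v, "'"))
    }
  }
  if (anyNA(df)) stop("dataset contains missing values; complete matrices are required")
  attr(df, "target") <- target
  class(df) <- c("tabular_dataset", "data.frame")
  df
}

#' Read a delimited dataset
#'
#' Reads a TSV or CSV matrix with a header row (rows = samples, columns =
#' variables; lines starting with `#` are ignored). Column kinds are taken
#' from `kinds` when declared; otherwise a column is inferred discrete when
#' it has at most 10 distinct integer-like values or is non-numeric, and
#' the inference is logged via `message()`. Ragged rows, duplicate headers,
#' a missing target column and missing values are each distinct errors.
#' `write_dataset()` followed by `read_dataset()` round-trips TSV files
#' byte-stably.
#'
#' @param path input file.
#' @param format `"tsv"` or `"csv"`.
#' @param target phenotype column name.
#' @param kinds optional named character vector as in [tabular_dataset()];
#'   `NULL` means infer.
#' @param quiet suppress inference messages.
#' @return a [tabular_dataset()].
#' @export
read_dataset <- function(path, format = c("tsv", "csv"), target,
                         kinds = NULL, quiet = FALSE) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  if (!file.exists(path)) stop("no such file: ", path)
  fields <- utils::count.fields(path, sep = sep, comment.char = "#",
                                quote = "")
  if (length(unique(fields)) > 1L)
    stop("ragged rows: lines have ", paste(unique(fields), collapse = ", "),
         " fields")
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (anyDuplicated(names(df)))
    stop("duplicate header column(s): ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  if (!target %in% names(df))
    stop("file has no target column '", target, "'")
  if (any(vapply(df, function(x) any(x == "" | x == "NA"), logical(1))))
    stop("dataset contains missing values; complete matrices are required")
  if (is.null(kinds)) {
    kinds <- vapply(names(df), function(v) {
      x <- df[[v]]
      num <- suppressWarnings(as.numeric(x))
      if (anyNA(num)) return("discrete")
      intlike <- all(abs(num - round(num)) < 1e-9)
      if (intlike && length(unique(num)) <= 10L) "discrete" else "continuous"
    }, character(1))
    if (!quiet)
      message("inferred kinds: ",
              sum(kinds == "discrete"), " discrete, ",
              sum(kinds == "continuous"), " continuous column(s)")
  } else {
    missing_kind <- setdiff(names(df), names(kinds))
    if (length(missing_kind))
      stop("kinds declared but missing for column(s): ",
           paste(missing_kind, collapse = ", "))
  }
  tabular_dataset(df, target = target, kinds = kinds)
}

#' Write a dataset as delimited text
#'
#' @param data a [tabular_dataset()] or plain data frame.
#' @param path output file.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  utils::write.table(data, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
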