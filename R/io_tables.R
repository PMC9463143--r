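#' Write a tabular result as TSV
#'
#' Tab-delimited with a header row; missing values are written as `.`.
#' Doubles are written with 15 significant digits so that a write/read
#' round trip is the identity up to floating-point text representation.
#'
#' @param table A data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(table, path) {
  df <- as.data.frame(table)
  for (j in seq_along(df)) {
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(x) paste(x, collapse = ","),
                        character(1))
    if (is.double(df[[j]])) {
      x <- df[[j]]
      s <- vapply(x, function(v) {
        if (is.na(v)) { if (is.nan(v)) "NaN" else "." }
        else format(v, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
      df[[j]] <- s
    } else {
      df[[j]] <- as.character(df[[j]])
      df[[j]][is.na(df[[j]])] <- "."
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#'
#' @param path Input file.
#' @param col_types Named character vector of declared column types
#'   (`"character"`, `"integer"`, `"double"`, `"logical"`); columns not
#'   named are read as character. When given, the file header must match
#'   `names(col_types)` exactly (schema check).
#' @return data.frame.
#' @export
read_tsv_table <- function(path, col_types = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = ".",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(col_types)) {
    if (!identical(names(df), names(col_types)))
      stop("schema mismatch: header is [", paste(names(df), collapse = ", "),
           "], declared [", paste(names(col_types), collapse = ", "), "]")
    for (j in names(col_types)) {
      df[[j]] <- switch(col_types[[j]],
                        character = df[[j]],
                        integer = as.integer(df[[j]]),
                        double = as.numeric(df[[j]]),
                        logical = as.logical(df[[j]]),
                        stop("unknown column type: ", col_types[[j]]))
    }
  }
  df
}
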