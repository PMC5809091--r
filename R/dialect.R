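#' Describe the dialect of a delimited text file
#'
#' A dialect bundles the parsing parameters for one input file: the field
#' delimiter, an optional comment character (lines starting with it are
#' skipped), the symbol that denotes a missing value, the header policy and
#' an optional quote character.
#'
#' With `header = "auto"` the first non-comment row is taken as the header
#' exactly when at least one of its cells fails numeric parsing while the
#' cell below it (same column, next row) parses as a number; otherwise
#' columns are auto-named `col_1`, `col_2`, ... A single-row file is never
#' auto-promoted to a header.
#'
#' @param delimiter Single field-separator character (default tab).
#' @param comment_char Single character starting comment lines, or `NULL`
#'   for none. Must differ from `delimiter`.
#' @param missing_symbol Text that marks a missing cell; may be `""`, in
#'   which case empty cells are missing.
#' @param header One of `"auto"`, `"first_row"`, `"none"`.
#' @param quote_char Single quoting character (fields wrapped in it may
#'   contain the delimiter), or `NULL` for no quote handling.
#' @return A `dialect` object.
#' @examples
#' dialect(delimiter = ",", comment_char = "#", missing_symbol = "NA")
#' @export
dialect <- function(delimiter = "\t", comment_char = NULL,
                    missing_symbol = "",
                    header = c("auto", "first_row", "none"),
                    quote_char = NULL) {
  header <- match.arg(header)
  if (nchar(delimiter) != 1L)
    gt_spec_error("delimiter must be a single character, got %s",
                  deparse(delimiter))
  if (!is.null(comment_char)) {
    if (nchar(comment_char) != 1L)
      gt_spec_error("comment_char must be a single character")
    if (identical(comment_char, delimiter))
      gt_spec_error("comment_char must differ from delimiter")
  }
  if (!is.null(quote_char) && nchar(quote_char) != 1L)
    gt_spec_error("quote_char must be a single character")
  structure(
    list(delimiter = delimiter, comment_char = comment_char,
         missing_symbol = as.character(missing_symbol), header = header,
         quote_char = quote_char),
    class = "dialect"
  )
}

#' @export
print.dialect <- function(x, ...) {
  cat(sprintf(
    "<dialect: delimiter=%s comment=%s missing=%s header=%s quote=%s>\n",
    deparse(x$delimiter),
    if (is.null(x$comment_char)) "none" else deparse(x$comment_char),
    deparse(x$missing_symbol), x$header,
    if (is.null(x$quote_char)) "none" else deparse(x$quote_char)))
  invisible(x)
}
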