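#' @title The universal table
#'
#' @description
#' Every operation in genotab consumes and produces a `gtable`: an ordered set
#' of equal-length columns of cells, a per-row provenance label naming the
#' source file each row came from, and an optional location schema declaring
#' which columns carry genomic coordinates (see [location_schema()]).
#'
#' Cells are stored verbatim as character strings; `NA` is the missing-value
#' sentinel and is distinct from the empty string. Each column additionally
#' carries an inferred type (`"integer"`, `"real"`, `"flag"` or `"text"`)
#' used by numeric predicates and export validation; typing never rewrites
#' the stored text, so files are compared and re-exported as text.
#'
#' @name gtable
NULL

# Internal constructor. `data` is a named list of equal-length character
# vectors; validates rectangularity on every construction so no operation can
# emit a ragged table.
new_gtable <- function(data, provenance, schema = NULL, types = NULL) {
  stopifnot(is.list(data))
  lens <- vapply(data, length, 0L)
  if (length(lens) && any(lens != lens[[1L]]))
    gt_structural_error("columns have unequal lengths: %s",
                        paste(unique(lens), collapse = ", "))
  nr <- if (length(lens)) lens[[1L]] else 0L
  if (length(provenance) == 1L) provenance <- rep(provenance, nr)
  if (length(provenance) != nr)
    gt_structural_error("provenance has %d entries for %d rows",
                        length(provenance), nr)
  if (is.null(types))
    types <- vapply(data, infer_column_type, "")
  structure(
    list(data = data, provenance = as.character(provenance),
         schema = schema, types = types),
    class = "gtable"
  )
}

#' Build a table from column names and a grid of cells
#'
#' @param column_names Character vector of column names; duplicates are
#'   resolved by appending `_2`, `_3`, ... to later occurrences.
#' @param rows A list of rows (each a vector with one cell per column), or a
#'   data frame / matrix. Cells are coerced to character; `NA` marks missing.
#' @param source_label Provenance label recorded for every row (typically the
#'   source file's basename).
#' @return A [gtable].
#' @examples
#' t <- make_table(c("gene", "score"), list(c("TP53", "0.9"), c("EGFR", "0.2")), "demo")
#' n_rows(t)
#' @export
make_table <- function(column_names, rows, source_label = "memory") {
  column_names <- as.character(column_names)
  nc <- length(column_names)
  if (is.data.frame(rows) || is.matrix(rows)) {
    rows <- lapply(seq_len(nrow(rows)), function(i) unlist(rows[i, ], use.names = FALSE))
  }
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != nc)
      gt_structural_error("row %d has %d cells, expected %d",
                          i, length(rows[[i]]), nc)
  }
  column_names <- uniquify_names(column_names)
  data <- if (length(rows)) {
    grid <- matrix(as.character(unlist(lapply(rows, as.character))),
                   nrow = length(rows), ncol = nc, byrow = TRUE)
    stats::setNames(lapply(seq_len(nc), function(j) grid[, j]), column_names)
  } else {
    stats::setNames(rep(list(character(0)), nc), column_names)
  }
  new_gtable(data, source_label)
}

# Resolve duplicate names by appending _2, _3, ... (first occurrence keeps
# the bare name); suffixed names that still collide keep incrementing.
uniquify_names <- function(names) {
  out <- character(length(names))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    nm <- names[[i]]
    if (!is.null(seen[[nm]])) {
      k <- seen[[nm]] + 1L
      cand <- paste0(nm, "_", k)
      while (!is.null(seen[[cand]])) {
        k <- k + 1L
        cand <- paste0(nm, "_", k)
      }
      seen[[nm]] <- k
      nm <- cand
    }
    seen[[nm]] <- 1L
    out[[i]] <- nm
  }
  out
}

#' Deterministic automatic column names
#'
#' Used whenever an input file carries no header: columns are named
#' `col_1` ... `col_n` (no zero padding).
#'
#' @param n Number of columns (0 gives an empty vector).
#' @return Character vector of length `n`.
#' @export
auto_name_columns <- function(n) {
  if (n == 0) return(character(0))
  paste0("col_", seq_len(n))
}

#' Infer the type of a column of cells
#'
#' A column is `integer` if every non-missing cell parses as an integer,
#' `real` if every non-missing cell parses as a number, `flag` if every
#' non-missing cell is `TRUE`/`FALSE` (as produced by VCF INFO flag
#' expansion), and `text` otherwise. An all-missing column is `text`.
#' Inference is idempotent and never alters the stored cells.
#'
#' @param values Character vector of cells (`NA` = missing).
#' @return One of `"integer"`, `"real"`, `"flag"`, `"text"`.
#' @export
infer_column_type <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return("text")
  if (all(v %in% c("TRUE", "FALSE"))) return("flag")
  if (all(grepl("^[+-]?[0-9]+$", v))) return("integer")
  num <- suppressWarnings(as.numeric(v))
  if (!anyNA(num)) return("real")
  "text"
}

#' @rdname gtable
#' @param x A `gtable`.
#' @export
n_rows <- function(x) {
  stopifnot(inherits(x, "gtable"))
  if (length(x$data)) length(x$data[[1L]]) else 0L
}

#' @rdname gtable
#' @export
column_names <- function(x) names(x$data)

#' @rdname gtable
#' @export
column_types <- function(x) x$types

#' @rdname gtable
#' @param name Column name.
#' @export
column_values <- function(x, name) {
  if (!name %in% names(x$data))
    gt_schema_error("no column named '%s'", name)
  x$data[[name]]
}

#' @rdname gtable
#' @export
provenance <- function(x) x$provenance

#' @rdname gtable
#' @export
location_schema_of <- function(x) x$schema

#' Attach a location schema to a table
#'
#' @param x A [gtable].
#' @param schema A [location_schema()] (or `NULL` to clear). All columns the
#'   schema names must exist in the table.
#' @return The table with the schema attached.
#' @export
set_location_schema <- function(x, schema) {
  stopifnot(inherits(x, "gtable"))
  if (!is.null(schema)) {
    stopifnot(inherits(schema, "location_schema"))
    need <- c(schema$column_names, schema$strand_column)
    miss <- setdiff(need, column_names(x))
    if (length(miss))
      gt_schema_error("schema names absent column(s): %s",
                      paste(miss, collapse = ", "))
  }
  x$schema <- schema
  x
}

# Row subset preserving provenance, schema and column types.
gt_subset_rows <- function(x, idx) {
  data <- lapply(x$data, `[`, idx)
  new_gtable(data, x$provenance[idx], schema = x$schema, types = x$types)
}

# Replace the data of a table, re-inferring types.
gt_with_data <- function(x, data, provenance = NULL, schema = NULL) {
  new_gtable(data, provenance %||% x$provenance, schema = schema %||% x$schema)
}

#' @export
print.gtable <- function(x, n = 6L, ...) {
  cat(sprintf("<gtable: %d rows x %d columns>\n", n_rows(x), length(x$data)))
  if (length(x$data)) {
    hdr <- paste0(names(x$data), " <", x$types, ">")
    cat(" ", paste(hdr, collapse = " | "), "\n")
    for (i in seq_len(min(n, n_rows(x)))) {
      cells <- vapply(x$data, function(col) {
        v <- col[[i]]
        if (is.na(v)) "<NA>" else v
      }, "")
      cat(" ", paste(cells, collapse = " | "), "\n")
    }
    if (n_rows(x) > n) cat(sprintf("  ... %d more rows\n", n_rows(x) - n))
  }
  invisible(x)
}

#' @export
dim.gtable <- function(x) c(n_rows(x), length(x$data))

#' Convert a table to a typed data frame
#'
#' Integer columns become `integer`, real columns `numeric`, flag columns
#' `logical`; text columns stay character. Missing cells become `NA`.
#'
#' @param x A [gtable].
#' @param row.names,optional,... Ignored (standard generic arguments).
#' @export
as.data.frame.gtable <- function(x, row.names = NULL, optional = FALSE, ...) {
  cols <- lapply(seq_along(x$data), function(j) {
    v <- x$data[[j]]
    switch(x$types[[j]],
      integer = {
        iv <- suppressWarnings(as.integer(v))
        # values beyond 32-bit integer range fall back to double
        if (any(!is.na(v) & is.na(iv))) as.numeric(v) else iv
      },
      real = as.numeric(v),
      flag = as.logical(v),
      v
    )
  })
  names(cols) <- names(x$data)
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE,
                optional = TRUE)
}
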