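#' Build a row predicate on one column
#'
#' Numeric comparisons (`lt`, `le`, `gt`, `ge`) require the column to be
#' numeric-typed and parse both cell and operand as reals. `eq`/`ne` compare
#' text after trimming surrounding whitespace; `contains` is a
#' case-sensitive substring test; `in_list` tests trimmed membership in a
#' non-empty text list. Rows whose cell is missing cannot certify a
#' condition: `on_missing = "drop"` (the default) excludes them,
#' `"keep"` retains them.
#'
#' @param column Column name.
#' @param op One of `eq`, `ne`, `lt`, `le`, `gt`, `ge`, `contains`,
#'   `in_list`.
#' @param operand A single value, or a character vector for `in_list`.
#' @param on_missing `"drop"` or `"keep"`.
#' @return A `predicate` object for [filter_rows()].
#' @examples
#' predicate("score", "gt", 0.85)
#' @export
predicate <- function(column, op = c("eq", "ne", "lt", "le", "gt", "ge",
                                     "contains", "in_list"),
                      operand, on_missing = c("drop", "keep")) {
  op <- match.arg(op)
  on_missing <- match.arg(on_missing)
  if (op == "in_list") {
    operand <- as.character(operand)
    if (!length(operand))
      gt_spec_error("in_list needs a non-empty value list")
  } else {
    if (length(operand) != 1L)
      gt_spec_error("op '%s' needs a single operand", op)
    operand <- as.character(operand)
  }
  structure(list(column = column, op = op, operand = operand,
                 on_missing = on_missing),
            class = "predicate")
}

eval_predicate <- function(table, pred) {
  stopifnot(inherits(pred, "predicate"))
  if (!pred$column %in% column_names(table))
    gt_schema_error("no column named '%s'", pred$column)
  cells <- column_values(table, pred$column)
  miss <- is.na(cells)
  sat <- logical(length(cells))
  if (pred$op %in% c("lt", "le", "gt", "ge")) {
    if (!column_types(table)[[pred$column]] %in% c("integer", "real"))
      gt_type_error("numeric predicate '%s' on non-numeric column '%s' (type %s)",
                    pred$op, pred$column, column_types(table)[[pred$column]])
    x <- suppressWarnings(as.numeric(cells))
    o <- suppressWarnings(as.numeric(pred$operand))
    if (is.na(o))
      gt_type_error("operand '%s' is not numeric", pred$operand)
    sat <- switch(pred$op, lt = x < o, le = x <= o, gt = x > o, ge = x >= o)
    sat[is.na(sat)] <- FALSE
  } else if (pred$op %in% c("eq", "ne")) {
    eq <- trimws(cells) == trimws(pred$operand)
    eq[miss] <- FALSE
    sat <- if (pred$op == "eq") eq else !eq
  } else if (pred$op == "contains") {
    sat <- grepl(pred$operand, cells, fixed = TRUE)
    sat[miss] <- FALSE
  } else {
    sat <- trimws(cells) %in% trimws(pred$operand)
    sat[miss] <- FALSE
  }
  sat[miss] <- (pred$on_missing == "keep")
  sat
}

#' Filter rows by one or more column predicates
#'
#' @param table A [gtable].
#' @param predicates A list of [predicate()]s (a single predicate is also
#'   accepted). An empty list keeps the table unchanged.
#' @param combine `"all"` (conjunction) or `"any"` (disjunction).
#' @return The table restricted to satisfying rows, order preserved.
#' @export
filter_rows <- function(table, predicates, combine = c("all", "any")) {
  combine <- match.arg(combine)
  if (inherits(predicates, "predicate")) predicates <- list(predicates)
  if (!length(predicates)) return(table)
  sats <- lapply(predicates, function(p) eval_predicate(table, p))
  keep <- Reduce(if (combine == "all") `&` else `|`, sats)
  gt_subset_rows(table, which(keep))
}

#' Filter rows by an external list of values
#'
#' The list file holds one value per line; blank lines and `#` comment
#' lines are ignored; values and cells are compared as trimmed text. A
#' missing cell is never a member of the list.
#'
#' @param table A [gtable].
#' @param column Column to test.
#' @param list_path Path to the value-list file (or a character vector of
#'   values given directly).
#' @param negate Keep rows whose cell is NOT in the list.
#' @return The filtered table.
#' @export
filter_by_list <- function(table, column, list_path, negate = FALSE) {
  values <- if (length(list_path) == 1L && file.exists(list_path)) {
    read_lines_any(list_path)
  } else if (length(list_path) >= 1L && !any(file.exists(list_path))) {
    # treat as in-memory values only when clearly not a path
    if (length(list_path) == 1L && grepl("[/\\\\]|\\.txt$|\\.lst$", list_path))
      gt_io_error("cannot read '%s': no such file", list_path)
    as.character(list_path)
  } else as.character(list_path)
  values <- trimws(values)
  values <- values[nzchar(values) & !startsWith(values, "#")]
  if (!length(values))
    gt_spec_error("value list is empty after removing blanks and comments")
  cells <- trimws(column_values(table, column))
  member <- !is.na(cells) & cells %in% values
  keep <- if (negate) !member else member
  gt_subset_rows(table, which(keep))
}

#' Specify criteria-file filtering
#'
#' An external track (any coordinate-bearing format) defines regions; data
#' rows are kept or dropped according to whether they overlap at least one
#' criteria interval. Criteria rows can be pre-filtered by a predicate
#' (e.g. conservation score > 0.85) before indexing.
#'
#' @param criteria_table A [gtable] with a location schema (typically from
#'   [read_track()]).
#' @param polarity `"keep_overlapping"` or `"drop_overlapping"`.
#' @param min_fraction Minimum overlap as a fraction of the data row's
#'   interval.
#' @param criteria_predicate Optional [predicate()] applied to criteria rows
#'   before indexing.
#' @return A `criteria_spec`.
#' @export
criteria_spec <- function(criteria_table,
                          polarity = c("keep_overlapping", "drop_overlapping"),
                          min_fraction = 0, criteria_predicate = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(criteria_table, "gtable"))
  if (is.null(location_schema_of(criteria_table)))
    gt_schema_error("criteria table has no location schema")
  if (!is.null(criteria_predicate))
    stopifnot(inherits(criteria_predicate, "predicate"))
  structure(list(criteria_table = criteria_table, polarity = polarity,
                 min_fraction = min_fraction,
                 criteria_predicate = criteria_predicate),
            class = "criteria_spec")
}

#' Filter rows by overlap with an external criteria track
#'
#' @param table A [gtable] with a location schema.
#' @param spec A [criteria_spec()].
#' @return The filtered table, row order preserved. For the same spec,
#'   `keep_overlapping` and `drop_overlapping` partition the input rows.
#' @export
filter_by_criteria <- function(table, spec) {
  stopifnot(inherits(spec, "criteria_spec"))
  if (is.null(location_schema_of(table)))
    gt_schema_error("table has no location schema")
  crit <- spec$criteria_table
  if (!is.null(spec$criteria_predicate))
    crit <- filter_rows(crit, list(spec$criteria_predicate), "all")
  ci <- extract_intervals(crit)
  di <- extract_intervals(table)
  hits <- query_index(build_interval_index(ci), di)
  hits <- filter_hits(hits, di, ci, spec$min_fraction)
  overlapping <- unique(hits$query)
  keep <- if (spec$polarity == "keep_overlapping") {
    sort(overlapping)
  } else {
    setdiff(seq_len(n_rows(table)), overlapping)
  }
  gt_subset_rows(table, keep)
}

#' Specify a sample-presence filter
#'
#' One to four columns identify the sample a row belongs to; the remaining
#' (or explicitly given) identity columns define the record (e.g. a
#' variant). A record is kept when it is present in at least (or at most)
#' the given fraction of samples.
#'
#' @param sample_columns 1-4 column names whose combined cells name the
#'   sample.
#' @param identity_columns Columns defining record identity; default: all
#'   non-sample columns.
#' @param threshold Fraction of samples in `(0, 1]`.
#' @param direction `"at_least"` or `"at_most"`.
#' @param total_samples Optional externally declared sample count; by
#'   default the distinct sample keys observed in the table.
#' @return A `sample_spec`.
#' @export
sample_spec <- function(sample_columns, identity_columns = NULL,
                        threshold = 0.5,
                        direction = c("at_least", "at_most"),
                        total_samples = NULL) {
  direction <- match.arg(direction)
  if (length(sample_columns) < 1L || length(sample_columns) > 4L)
    gt_spec_error("sample_columns must name 1-4 columns, got %d",
                  length(sample_columns))
  if (!is.null(identity_columns) &&
      length(intersect(sample_columns, identity_columns)))
    gt_spec_error("sample and identity columns must be disjoint")
  if (threshold <= 0 || threshold > 1)
    gt_spec_error("threshold must be in (0, 1]")
  structure(list(sample_columns = sample_columns,
                 identity_columns = identity_columns,
                 threshold = threshold, direction = direction,
                 total_samples = total_samples),
            class = "sample_spec")
}

row_key <- function(table, cols, na_void = TRUE) {
  parts <- lapply(cols, function(cn) column_values(table, cn))
  any_na <- Reduce(`|`, lapply(parts, is.na))
  parts <- lapply(parts, function(p) ifelse(is.na(p), "\x01NA\x01", p))
  key <- do.call(paste, c(parts, sep = "\r"))
  if (na_void) key[any_na] <- NA_character_
  key
}

#' Filter records by presence across samples
#'
#' Presence of a record (identity tuple) is the number of distinct sample
#' keys among its rows divided by the total number of samples (distinct
#' sample keys observed in the whole table, unless overridden in the spec).
#' All rows of qualifying records are kept, order preserved. Rows whose
#' sample cells are missing contribute no sample key.
#'
#' @param table A non-empty [gtable].
#' @param spec A [sample_spec()].
#' @return The filtered table.
#' @export
filter_by_sample_presence <- function(table, spec) {
  stopifnot(inherits(spec, "sample_spec"))
  if (!n_rows(table)) gt_data_error("table is empty")
  for (cn in spec$sample_columns) if (!cn %in% column_names(table))
    gt_schema_error("no column named '%s'", cn)
  id_cols <- spec$identity_columns %||%
    setdiff(column_names(table), spec$sample_columns)
  for (cn in id_cols) if (!cn %in% column_names(table))
    gt_schema_error("no column named '%s'", cn)
  skey <- row_key(table, spec$sample_columns)
  total <- spec$total_samples %||% length(unique(skey[!is.na(skey)]))
  if (total == 0)
    gt_data_error("no sample keys observed (all sample cells missing)")
  ikey <- row_key(table, id_cols, na_void = FALSE)
  ok_rows <- !is.na(skey)
  presence <- tapply(skey[ok_rows], ikey[ok_rows],
                     function(s) length(unique(s)) / total)
  frac <- presence[ikey]
  frac[is.na(frac)] <- 0
  keep <- if (spec$direction == "at_least") frac >= spec$threshold
          else frac <= spec$threshold
  gt_subset_rows(table, which(unname(keep)))
}
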