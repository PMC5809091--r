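#' Specify a horizontal join
#'
#' @param mode `"inner"` drops left rows with no match; `"left_outer"` keeps
#'   them with the right-hand cells missing.
#' @param predicate `"overlap"` (genomic overlap with `min_fraction`),
#'   `"exact_interval"` (canonical intervals identical), or
#'   `"key_equality"` (1-4 key-column pairs compared as trimmed text).
#' @param min_fraction For `"overlap"`: required overlap as a fraction of
#'   the left interval's length.
#' @param key_columns For `"key_equality"`: a named character vector
#'   mapping left column names to right column names (an unnamed vector
#'   uses the same name on both sides). At most 4 pairs.
#' @param multiplicity `"expand_pairs"` emits one output row per matching
#'   pair; `"first_match"` emits at most one per left row (lowest right
#'   row index wins).
#' @param match_strand Restrict overlap joins to equal strands.
#' @return A `join_spec`.
#' @export
join_spec <- function(mode = c("inner", "left_outer"),
                      predicate = c("overlap", "exact_interval", "key_equality"),
                      min_fraction = 0, key_columns = NULL,
                      multiplicity = c("expand_pairs", "first_match"),
                      match_strand = FALSE) {
  mode <- match.arg(mode)
  predicate <- match.arg(predicate)
  multiplicity <- match.arg(multiplicity)
  if (min_fraction < 0 || min_fraction > 1)
    gt_spec_error("min_fraction must be in [0, 1]")
  if (predicate == "key_equality") {
    if (is.null(key_columns) || length(key_columns) < 1L)
      gt_spec_error("key_equality needs at least 1 key column pair")
    if (length(key_columns) > 4L)
      gt_spec_error("at most 4 key column pairs are supported (max 4), got %d",
                    length(key_columns))
    if (is.null(names(key_columns)))
      names(key_columns) <- key_columns
    nm <- names(key_columns)
    nm[!nzchar(nm)] <- key_columns[!nzchar(nm)]
    names(key_columns) <- nm
  }
  structure(
    list(mode = mode, predicate = predicate, min_fraction = min_fraction,
         key_columns = key_columns, multiplicity = multiplicity,
         match_strand = match_strand),
    class = "join_spec"
  )
}

# Assemble the joined table from matched (left, right) row pairs. Output
# columns are left's followed by right's (collisions suffixed); row order is
# ascending (left index, right index); merged provenance is
# "left_label+right_label"; unmatched left rows (left_outer) keep their own
# label with right cells missing.
assemble_join <- function(left, right, pairs, mode, multiplicity) {
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$left, pairs$right), , drop = FALSE]
    if (multiplicity == "first_match")
      pairs <- pairs[!duplicated(pairs$left), , drop = FALSE]
  }
  li <- pairs$left
  ri <- pairs$right
  if (mode == "left_outer") {
    unmatched <- setdiff(seq_len(n_rows(left)), li)
    li <- c(li, unmatched)
    ri <- c(ri, rep(NA_integer_, length(unmatched)))
    ord <- order(li, ri, na.last = TRUE)
    li <- li[ord]; ri <- ri[ord]
  }
  right_names <- uniquify_names(c(column_names(left), column_names(right)))
  right_names <- right_names[seq_along(column_names(right)) + length(column_names(left))]
  ldata <- lapply(left$data, `[`, li)
  rdata <- lapply(right$data, function(col) {
    out <- rep(NA_character_, length(ri))
    out[!is.na(ri)] <- col[ri[!is.na(ri)]]
    out
  })
  names(rdata) <- right_names
  prov <- ifelse(is.na(ri), provenance(left)[li],
                 paste0(provenance(left)[li], "+", provenance(right)[pmax(ri, 1L)]))
  new_gtable(c(ldata, rdata), prov, schema = location_schema_of(left))
}

#' Join two tables by genomic location
#'
#' Both tables must carry a location schema; their rows are matched on
#' canonical intervals, either by overlap (with optional minimum fraction of
#' the left interval) or by exact interval identity.
#'
#' @param left,right [gtable]s with location schemas.
#' @param spec A [join_spec()] with predicate `"overlap"` or
#'   `"exact_interval"`.
#' @return A [gtable]: left columns then right columns (name collisions
#'   suffixed), rows ordered by (left row, right row). The left table's
#'   schema is carried over.
#' @export
merge_by_location <- function(left, right, spec = join_spec()) {
  stopifnot(inherits(spec, "join_spec"))
  if (!spec$predicate %in% c("overlap", "exact_interval"))
    gt_spec_error("merge_by_location needs an overlap or exact_interval predicate")
  if (is.null(location_schema_of(left)))
    gt_schema_error("left table has no location schema")
  if (is.null(location_schema_of(right)))
    gt_schema_error("right table has no location schema")
  li <- extract_intervals(left)
  ri <- extract_intervals(right)
  if (spec$predicate == "overlap") {
    index <- build_interval_index(ri)
    hits <- query_index(index, li)
    hits <- filter_hits(hits, li, ri, spec$min_fraction, spec$match_strand)
    pairs <- data.frame(left = hits$query, right = hits$subject)
  } else {
    lkey <- paste(li$chrom, li$start, li$end, sep = "\r")
    rkey <- paste(ri$chrom, ri$start, ri$end, sep = "\r")
    rmap <- split(seq_along(rkey), rkey)
    matches <- rmap[lkey]
    lens <- lengths(matches)
    pairs <- data.frame(left = rep(seq_along(lkey), lens),
                        right = unlist(matches, use.names = FALSE) %||% integer(0))
  }
  assemble_join(left, right, pairs, spec$mode, spec$multiplicity)
}

#' Join two tables by up to four key columns
#'
#' Rows match iff every key-column pair is equal as text after trimming
#' surrounding whitespace. Missing never matches, including missing on both
#' sides. Numeric equality (`1` vs `1.0`) is deliberately not applied:
#' text files are compared as text.
#'
#' @param left,right [gtable]s.
#' @param spec A [join_spec()] with predicate `"key_equality"` and 1-4
#'   `key_columns`.
#' @return A [gtable] with the same contract as [merge_by_location()].
#' @export
merge_by_keys <- function(left, right, spec) {
  stopifnot(inherits(spec, "join_spec"))
  if (spec$predicate != "key_equality")
    gt_spec_error("merge_by_keys needs a key_equality predicate")
  lcols <- names(spec$key_columns)
  rcols <- unname(spec$key_columns)
  for (cn in lcols) if (!cn %in% column_names(left))
    gt_schema_error("left table has no column '%s'", cn)
  for (cn in rcols) if (!cn %in% column_names(right))
    gt_schema_error("right table has no column '%s'", cn)
  key_of <- function(tab, cols) {
    parts <- lapply(cols, function(cn) trimws(column_values(tab, cn)))
    any_na <- Reduce(`|`, lapply(parts, is.na))
    key <- do.call(paste, c(parts, sep = "\r"))
    key[any_na] <- NA_character_
    key
  }
  lkey <- key_of(left, lcols)
  rkey <- key_of(right, rcols)
  rmap <- split(seq_along(rkey)[!is.na(rkey)], rkey[!is.na(rkey)])
  matches <- rep(list(integer(0)), length(lkey))
  has <- !is.na(lkey) & lkey %in% names(rmap)
  matches[has] <- rmap[lkey[has]]
  lens <- lengths(matches)
  pairs <- data.frame(left = rep(seq_along(lkey), lens),
                      right = unlist(matches, use.names = FALSE) %||% integer(0))
  assemble_join(left, right, pairs, spec$mode, spec$multiplicity)
}

#' Stack tables vertically by column-name union
#'
#' The output's columns are the union of the inputs' column names in order
#' of first appearance; same-named columns are stacked; cells absent from a
#' source table are missing. Row provenance is preserved. Inputs may come
#' from entirely different formats.
#'
#' @param tables A non-empty list of [gtable]s.
#' @return A [gtable] with `sum(n_rows)` rows. The first input's location
#'   schema is carried over when its columns survive (they always do).
#' @export
append_tables <- function(tables) {
  if (inherits(tables, "gtable")) tables <- list(tables)
  if (!length(tables)) gt_spec_error("append needs at least one table")
  for (t in tables) stopifnot(inherits(t, "gtable"))
  all_names <- unique(unlist(lapply(tables, column_names)))
  data <- stats::setNames(lapply(all_names, function(nm) {
    unlist(lapply(tables, function(t) {
      if (nm %in% column_names(t)) column_values(t, nm)
      else rep(NA_character_, n_rows(t))
    }), use.names = FALSE)
  }), all_names)
  prov <- unlist(lapply(tables, provenance), use.names = FALSE)
  new_gtable(data, prov %||% character(0),
             schema = location_schema_of(tables[[1L]]))
}
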