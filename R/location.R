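#' Declare which columns of a table carry genomic coordinates
#'
#' Tables read from coordinate-bearing formats get a schema automatically;
#' arbitrary delimited tables can be given one so interval operations work
#' on them. The internal canonical convention is 0-based half-open
#' (BED-style); a schema records how to get there from the table's own
#' encoding.
#'
#' @param encoding How coordinates are encoded:
#'   `"three_column"` (chrom, start, end columns), `"chrom_pos"` (chrom and
#'   a single position column; interval length is taken from a `REF` column
#'   when one exists, else 1), or `"locus_string"` (one column holding
#'   `"chr:start-end"` text).
#' @param column_names The 3, 2 or 1 column names for the chosen encoding.
#' @param basis `"zero_half_open"` or `"one_closed"` — the convention the
#'   stored numbers use. Mandatory; there is no schema without a declared
#'   convention.
#' @param strand_column Optional name of a strand column (`+`, `-`, `.`).
#' @return A `location_schema` object.
#' @examples
#' location_schema("three_column", c("chrom", "start", "end"), "zero_half_open")
#' @export
location_schema <- function(encoding = c("three_column", "chrom_pos", "locus_string"),
                            column_names,
                            basis = c("zero_half_open", "one_closed"),
                            strand_column = NULL) {
  encoding <- match.arg(encoding)
  basis <- match.arg(basis)
  need <- switch(encoding, three_column = 3L, chrom_pos = 2L, locus_string = 1L)
  if (length(column_names) != need)
    gt_spec_error("encoding '%s' needs %d column name(s), got %d",
                  encoding, need, length(column_names))
  structure(
    list(encoding = encoding, column_names = as.character(column_names),
         basis = basis, strand_column = strand_column),
    class = "location_schema"
  )
}

#' @export
print.location_schema <- function(x, ...) {
  cat(sprintf("<location_schema: %s on (%s), %s%s>\n",
              x$encoding, paste(x$column_names, collapse = ", "), x$basis,
              if (is.null(x$strand_column)) ""
              else paste0(", strand=", x$strand_column)))
  invisible(x)
}

parse_coord <- function(values, what) {
  x <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(x) & !is.na(values) | is.na(values))
  if (length(bad))
    gt_data_error("row %d: cannot parse %s coordinate '%s'",
                  bad[[1L]], what, as.character(values[bad[[1L]]]))
  x
}

#' Extract canonical intervals from a table
#'
#' One interval per row, in the canonical 0-based half-open convention:
#' a 1-based closed start is converted via `start - 1`; a chrom/pos row
#' spans `len(REF)` bases when the table has a REF column (VCF-derived
#' tables), else 1; locus strings `"chr:start-end"` are interpreted in the
#' schema's declared basis. Zero-length intervals (insertion points) are
#' allowed.
#'
#' @param table A [gtable] with a location schema.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`
#'   (one row per table row).
#' @export
extract_intervals <- function(table) {
  schema <- location_schema_of(table)
  if (is.null(schema))
    gt_schema_error("table has no location schema")
  nr <- n_rows(table)
  off <- if (schema$basis == "one_closed") 1 else 0
  if (schema$encoding == "three_column") {
    cn <- schema$column_names
    chrom <- column_values(table, cn[[1L]])
    start <- parse_coord(column_values(table, cn[[2L]]), "start") - off
    end <- parse_coord(column_values(table, cn[[3L]]), "end")
  } else if (schema$encoding == "chrom_pos") {
    cn <- schema$column_names
    chrom <- column_values(table, cn[[1L]])
    pos <- parse_coord(column_values(table, cn[[2L]]), "position")
    len <- if ("REF" %in% column_names(table)) {
      ref <- column_values(table, "REF")
      ifelse(is.na(ref), 1L, nchar(ref))
    } else rep(1L, nr)
    start <- pos - off
    end <- start + len
  } else {
    loc <- column_values(table, schema$column_names[[1L]])
    m <- regexec("^(.+):([0-9]+)-([0-9]+)$", loc)
    parts <- regmatches(loc, m)
    bad <- which(lengths(parts) != 4L)
    if (length(bad))
      gt_data_error("row %d: cannot parse locus string '%s'",
                    bad[[1L]], as.character(loc[bad[[1L]]]))
    chrom <- vapply(parts, `[[`, "", 2L)
    start <- as.numeric(vapply(parts, `[[`, "", 3L)) - off
    end <- as.numeric(vapply(parts, `[[`, "", 4L))
  }
  if (any(!nzchar(chrom) | is.na(chrom)))
    gt_data_error("row %d: empty chromosome name",
                  which(!nzchar(chrom) | is.na(chrom))[[1L]])
  neg <- which(start < 0)
  if (length(neg))
    gt_data_error("row %d: negative start after convention conversion", neg[[1L]])
  rev <- which(end < start)
  if (length(rev))
    gt_data_error("row %d: end < start", rev[[1L]])
  strand <- if (!is.null(schema$strand_column)) {
    s <- column_values(table, schema$strand_column)
    ifelse(is.na(s) | !s %in% c("+", "-"), ".", s)
  } else rep(".", nr)
  data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Convert canonical intervals back to a declared convention
#'
#' @param intervals Data frame from [extract_intervals()].
#' @param basis Target convention.
#' @return The data frame with `start` shifted for `"one_closed"`.
#' @export
intervals_to_basis <- function(intervals, basis = c("zero_half_open", "one_closed")) {
  basis <- match.arg(basis)
  if (basis == "one_closed") intervals$start <- intervals$start + 1
  intervals
}

#' Overlap predicate between two intervals
#'
#' True iff the chromosomes match and the overlap length is positive and at
#' least `min_fraction` of the length of `a` (the left/query interval;
#' the fraction is not reciprocal). A zero-length `a` (insertion point)
#' overlaps `b` iff its point lies in `[start(b), end(b))`; a zero-length
#' `b` never overlaps anything.
#'
#' @param a,b Intervals: lists or one-row data frames with `chrom`, `start`,
#'   `end` in canonical 0-based half-open coordinates.
#' @param min_fraction Required overlap as a fraction of `length(a)`,
#'   in `[0, 1]`; 0 means any positive overlap.
#' @param match_strand If `TRUE`, also require equal strands (a `.` strand
#'   matches nothing but `.`).
#' @return Logical scalar.
#' @export
interval_overlaps <- function(a, b, min_fraction = 0, match_strand = FALSE) {
  if (!identical(as.character(a$chrom), as.character(b$chrom))) return(FALSE)
  if (match_strand &&
      !identical(as.character(a$strand %||% "."), as.character(b$strand %||% ".")))
    return(FALSE)
  as_ <- as.numeric(a$start); ae <- as.numeric(a$end)
  bs <- as.numeric(b$start); be <- as.numeric(b$end)
  if (ae == as_) return(as_ >= bs && as_ < be)
  ov <- min(ae, be) - max(as_, bs)
  ov > 0 && ov >= min_fraction * (ae - as_)
}

#' Build a query index over a set of intervals
#'
#' The index answers "which stored intervals overlap this query?" and is
#' equivalent to an exhaustive scan with [interval_overlaps()] at
#' `min_fraction = 0`. Backed by per-chromosome IRanges overlap trees;
#' zero-length stored intervals are excluded (they can never be overlapped)
#' and zero-length queries are evaluated with the insertion-point rule.
#'
#' @param intervals Data frame from [extract_intervals()].
#' @return An `interval_index`.
#' @export
build_interval_index <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  nonzero <- which(intervals$end > intervals$start)
  by_chrom <- split(nonzero, intervals$chrom[nonzero])
  trees <- lapply(by_chrom, function(idx) {
    list(idx = idx,
         ranges = IRanges::IRanges(start = intervals$start[idx] + 1L,
                                   end = intervals$end[idx]))
  })
  structure(list(intervals = intervals, trees = trees),
            class = "interval_index")
}

#' Query an interval index
#'
#' @param index An `interval_index` from [build_interval_index()].
#' @param queries Data frame of canonical intervals.
#' @return A data frame `(query, subject)` of index pairs, ascending by
#'   query then subject; `subject` refers to positions in the indexed
#'   interval set.
#' @export
query_index <- function(index, queries) {
  stopifnot(inherits(index, "interval_index"))
  if (!nrow(queries) || !length(index$trees))
    return(data.frame(query = integer(0), subject = integer(0)))
  # zero-length queries are widened to the single base at their point,
  # which realises the insertion-point rule under minoverlap = 1
  qs <- queries$start
  qe <- ifelse(queries$end > queries$start, queries$end, queries$start + 1)
  out_q <- integer(0); out_s <- integer(0)
  for (chrom in intersect(unique(queries$chrom), names(index$trees))) {
    qi <- which(queries$chrom == chrom)
    tree <- index$trees[[chrom]]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = qs[qi] + 1L, end = qe[qi]),
      tree$ranges, minoverlap = 1L)
    out_q <- c(out_q, qi[S4Vectors::queryHits(hits)])
    out_s <- c(out_s, tree$idx[S4Vectors::subjectHits(hits)])
  }
  ord <- order(out_q, out_s)
  data.frame(query = out_q[ord], subject = out_s[ord])
}

# Filter candidate (query, subject) pairs by the full overlap predicate;
# used wherever min_fraction > 0 or strand matching is requested.
filter_hits <- function(hits, queries, subjects, min_fraction = 0,
                        match_strand = FALSE) {
  if (!nrow(hits) || (min_fraction <= 0 && !match_strand)) return(hits)
  keep <- vapply(seq_len(nrow(hits)), function(k) {
    interval_overlaps(queries[hits$query[[k]], ], subjects[hits$subject[[k]], ],
                      min_fraction = min_fraction, match_strand = match_strand)
  }, TRUE)
  hits[keep, , drop = FALSE]
}
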