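#' Keep only the named columns, in the given order
#'
#' @param table A [gtable].
#' @param names Column names to keep (all must exist).
#' @return The reduced table; rows unchanged. The location schema is kept
#'   when all of its columns survive, otherwise cleared.
#' @export
select_columns <- function(table, names) {
  unknown <- setdiff(names, column_names(table))
  if (length(unknown))
    gt_schema_error("no column named '%s'", unknown[[1L]])
  data <- table$data[names]
  schema <- location_schema_of(table)
  if (!is.null(schema) &&
      !all(c(schema$column_names, schema$strand_column) %in% names))
    schema <- NULL
  new_gtable(data, provenance(table), schema = schema,
             types = table$types[names])
}

#' Drop duplicate rows, keeping first occurrences
#'
#' @param table A [gtable].
#' @param key_columns Columns that define row identity; `NULL` means all
#'   columns.
#' @return The deduplicated table, order preserved.
#' @export
deduplicate <- function(table, key_columns = NULL) {
  cols <- key_columns %||% column_names(table)
  unknown <- setdiff(cols, column_names(table))
  if (length(unknown))
    gt_schema_error("no column named '%s'", unknown[[1L]])
  if (!n_rows(table)) return(table)
  key <- row_key(table, cols, na_void = FALSE)
  gt_subset_rows(table, which(!duplicated(key)))
}

#' Export a table as tab-delimited text
#'
#' UTF-8, LF line endings, tab delimiter. Cells are written verbatim; a cell
#' (or column name) containing a tab or newline raises an export error
#' rather than being quoted. Missing cells render as `missing_symbol`.
#'
#' @param table A [gtable].
#' @param path Output file path.
#' @param write_header Write the column names as the first line?
#' @param missing_symbol Text standing in for missing cells (default: empty).
#' @return The path, invisibly.
#' @export
export_tab <- function(table, path, write_header = TRUE, missing_symbol = "") {
  nms <- column_names(table)
  if (any(grepl("[\t\n\r]", nms)))
    gt_export_error("column name '%s' contains a delimiter or newline",
                    nms[grepl("[\t\n\r]", nms)][[1L]])
  for (nm in nms) {
    v <- column_values(table, nm)
    bad <- which(grepl("[\t\n\r]", v))
    if (length(bad))
      gt_export_error("cell at row %d, column '%s' contains a delimiter or newline",
                      bad[[1L]], nm)
  }
  rows <- if (length(nms)) {
    m <- do.call(cbind, lapply(nms, function(nm) {
      v <- column_values(table, nm)
      ifelse(is.na(v), missing_symbol, v)
    }))
    apply(m, 1L, paste, collapse = "\t")
  } else character(0)
  lines <- c(if (write_header) paste(nms, collapse = "\t"), rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# ---- track format registry -------------------------------------------------
# For each export format: ordered field names, which are coordinate fields,
# the coordinate convention, per-field defaults ("." / "0" style constants;
# a few are derived per row from the interval), and which fields must be
# numeric when bound.

track_format_registry <- function() {
  bed12 <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
             "thickStart", "thickEnd", "itemRgb", "blockCount",
             "blockSizes", "blockStarts")
  bed6 <- bed12[1:6]
  peak_defaults <- c(name = ".", score = "0", signalValue = "0",
                     pValue = "-1", qValue = "-1")
  list(
    bed = list(fields = bed12, variable = TRUE, min_fields = 3L,
               basis = "zero_half_open",
               defaults = c(name = ".", score = "0", itemRgb = "0"),
               numeric = "score", clamp_score = TRUE),
    bed_detail = list(fields = c(bed12, "ID", "description"),
                      variable = TRUE, min_fields = 4L, tail_fields = 2L,
                      basis = "zero_half_open",
                      defaults = c(name = ".", score = "0", itemRgb = "0",
                                   ID = ".", description = "."),
                      numeric = "score", clamp_score = TRUE),
    bed6plus3 = list(fields = c(bed6, "level", "signif", "score2"),
                     basis = "zero_half_open",
                     defaults = c(name = ".", score = "0", level = "0",
                                  signif = "0", score2 = "0"),
                     numeric = "score", clamp_score = TRUE),
    narrowpeak = list(fields = c(bed6, "signalValue", "pValue", "qValue", "peak"),
                      basis = "zero_half_open",
                      defaults = c(peak_defaults, peak = "-1"),
                      numeric = "score", clamp_score = TRUE),
    broadpeak = list(fields = c(bed6, "signalValue", "pValue", "qValue"),
                     basis = "zero_half_open",
                     defaults = peak_defaults,
                     numeric = "score", clamp_score = TRUE),
    gappedpeak = list(fields = c(bed12, "signalValue", "pValue", "qValue"),
                      basis = "zero_half_open",
                      defaults = c(name = ".", score = "0", itemRgb = "0",
                                   signalValue = "0", pValue = "-1",
                                   qValue = "-1"),
                      numeric = "score", clamp_score = TRUE),
    peptide_mapping = list(fields = c(bed6, "rawScore", "spectrumId",
                                      "peptideRank", "peptideRepeatCount"),
                           basis = "zero_half_open",
                           defaults = c(name = ".", score = "0",
                                        rawScore = "0", spectrumId = ".",
                                        peptideRank = "0",
                                        peptideRepeatCount = "0"),
                           numeric = "score", clamp_score = TRUE),
    gff = list(fields = gff_field_names, basis = "one_closed",
               coord_fields = c(chrom = "seqname", start = "start", end = "end"),
               strand_field = "strand",
               defaults = c(source = ".", feature = "feature", score = ".",
                            frame = ".", attribute = "."),
               numeric = character(0), clamp_score = FALSE),
    psl = list(fields = psl_field_names, basis = "zero_half_open",
               coord_fields = c(chrom = "tName", start = "tStart", end = "tEnd"),
               strand_field = "strand",
               defaults = c(misMatches = "0", repMatches = "0", nCount = "0",
                            qNumInsert = "0", qBaseInsert = "0",
                            tNumInsert = "0", tBaseInsert = "0",
                            qName = ".", blockCount = "1"),
               numeric = character(0), clamp_score = FALSE),
    personal_genome_snp = list(
      fields = c("chrom", "chromStart", "chromEnd", "name",
                 "alleleCount", "alleleFreq", "alleleScores"),
      basis = "zero_half_open",
      defaults = c(name = "N", alleleCount = "1", alleleFreq = "0",
                   alleleScores = "0"),
      numeric = character(0), clamp_score = FALSE)
  )
}

#' Bind table columns to the fields of an export format
#'
#' Coordinate fields (chrom/start/end and, where present, strand) are always
#' derived from the table's canonical intervals and cannot be bound to raw
#' text columns. Every other field may be bound to a source column
#' (`bindings`), set to a constant (`constants`), or left to its canonical
#' default (name `.`, score `0`, strand `.`, narrowPeak peak `-1`, ...).
#'
#' @param format_name One of `tab`, `bed`, `bed_detail`, `psl`, `gff`,
#'   `personal_genome_snp`, `bed6plus3`, `narrowpeak`, `broadpeak`,
#'   `gappedpeak`, `peptide_mapping`.
#' @param bindings Named character vector: format field -> source column.
#' @param constants Named character vector: format field -> constant text.
#' @param schema Optional [location_schema()] overriding the table's own
#'   schema at export time.
#' @return A `column_mapping`.
#' @export
column_mapping <- function(format_name, bindings = character(),
                           constants = character(), schema = NULL) {
  registry <- track_format_registry()
  if (!format_name %in% c("tab", names(registry)))
    gt_spec_error("unknown export format '%s'", format_name)
  if (format_name != "tab") {
    fmt <- registry[[format_name]]
    coord <- fmt$coord_fields %||%
      c(chrom = "chrom", start = "chromStart", end = "chromEnd")
    strand_field <- fmt$strand_field %||%
      (if ("strand" %in% fmt$fields) "strand" else NULL)
    bad <- setdiff(names(bindings), setdiff(fmt$fields, coord))
    if (length(bad))
      gt_spec_error("cannot bind field '%s' for format %s%s", bad[[1L]],
                    format_name,
                    if (bad[[1L]] %in% coord)
                      " (coordinate fields are derived from intervals)" else "")
    bad <- setdiff(names(constants), setdiff(fmt$fields, coord))
    if (length(bad))
      gt_spec_error("cannot set constant for field '%s' of format %s",
                    bad[[1L]], format_name)
  }
  structure(list(format_name = format_name, bindings = bindings,
                 constants = constants, schema = schema),
            class = "column_mapping")
}

#' Export a table to a UCSC/ENCODE track format
#'
#' Coordinates are emitted in the target format's native convention (BED
#' family and PSL: 0-based half-open; GFF: 1-based closed), derived from the
#' table's canonical intervals. Unbound optional fields get canonical
#' defaults. Every output line has exactly the format's field count. BED
#' family scores bound to a column must be numeric and are clamped to
#' [0, 1000] with a warning, as the genome browsers require.
#'
#' @param table A [gtable] with a location schema (or a mapping carrying
#'   one).
#' @param mapping A [column_mapping()].
#' @param path Output file path.
#' @param track_line Optional `track ...` declaration written first,
#'   verbatim.
#' @return The path, invisibly.
#' @export
export_track <- function(table, mapping, path, track_line = NULL) {
  stopifnot(inherits(mapping, "column_mapping"))
  if (mapping$format_name == "tab") {
    if (!is.null(track_line))
      gt_spec_error("tab export takes no track line")
    return(export_tab(table, path))
  }
  registry <- track_format_registry()
  fmt <- registry[[mapping$format_name]]
  tab <- table
  if (!is.null(mapping$schema)) tab <- set_location_schema(tab, mapping$schema)
  if (is.null(location_schema_of(tab)))
    gt_export_error("mandatory field 'chrom' is unbound: table has no location schema")
  iv <- extract_intervals(tab)
  out_iv <- intervals_to_basis(iv, fmt$basis)
  if (any(out_iv$end < out_iv$start))
    gt_export_error("row %d: end < start after conversion to %s",
                    which(out_iv$end < out_iv$start)[[1L]], fmt$basis)
  nr <- nrow(out_iv)

  coord <- fmt$coord_fields %||%
    c(chrom = "chrom", start = "chromStart", end = "chromEnd")
  strand_field <- fmt$strand_field %||%
    (if ("strand" %in% fmt$fields) "strand" else NULL)

  fields <- fmt$fields
  span <- iv$end - iv$start
  derived_default <- function(field) {
    switch(field,
      thickStart = format_coord(out_iv$start),
      thickEnd = format_coord(out_iv$end),
      blockCount = rep("1", nr),
      blockSizes = paste0(format_coord(pmax(span, 0)), ","),
      blockStarts = rep("0,", nr),
      matches = format_coord(span),
      qSize = format_coord(span),
      qStart = rep("0", nr),
      qEnd = format_coord(span),
      tSize = format_coord(out_iv$end),
      qStarts = rep("0,", nr),
      tStarts = paste0(format_coord(out_iv$start), ","),
      NULL)
  }

  cols <- stats::setNames(vector("list", length(fields)), fields)
  for (field in fields) {
    if (field == coord[["chrom"]]) { cols[[field]] <- out_iv$chrom; next }
    if (field == coord[["start"]]) { cols[[field]] <- format_coord(out_iv$start); next }
    if (field == coord[["end"]]) { cols[[field]] <- format_coord(out_iv$end); next }
    if (!is.null(strand_field) && field == strand_field &&
        !field %in% names(mapping$bindings) &&
        !field %in% names(mapping$constants)) {
      cols[[field]] <- iv$strand
      next
    }
    if (field %in% names(mapping$bindings)) {
      src <- mapping$bindings[[field]]
      if (!src %in% column_names(tab))
        gt_schema_error("no column named '%s' (bound to field '%s')", src, field)
      v <- column_values(tab, src)
      if (field %in% fmt$numeric || (field == "score" && fmt$clamp_score)) {
        if (!column_types(tab)[[src]] %in% c("integer", "real"))
          gt_export_error("field '%s' bound to non-numeric column '%s'",
                          field, src)
      }
      cols[[field]] <- ifelse(is.na(v), ".", v)
    } else if (field %in% names(mapping$constants)) {
      cols[[field]] <- rep(as.character(mapping$constants[[field]]), nr)
    } else {
      d <- derived_default(field)
      if (is.null(d)) {
        d0 <- fmt$defaults[field]
        d <- rep(if (is.na(d0)) "0" else unname(d0), nr)
      }
      cols[[field]] <- d
    }
  }

  if (fmt$clamp_score && "score" %in% names(mapping$bindings)) {
    x <- suppressWarnings(as.numeric(cols[["score"]]))
    x[is.na(x)] <- 0
    if (any(x < 0 | x > 1000)) {
      warning("BED scores outside [0, 1000] clamped for browser validity",
              call. = FALSE)
      x <- pmin(pmax(x, 0), 1000)
    }
    cols[["score"]] <- format_coord(x)
  }

  # variable-width BED: emit up to the highest bound/filled field,
  # never fewer than min_fields; BED detail always appends its two
  # trailing fields after the BED block.
  if (isTRUE(fmt$variable)) {
    tail_n <- fmt$tail_fields %||% 0L
    bed_fields <- fields[seq_len(length(fields) - tail_n)]
    explicit <- c(names(mapping$bindings), names(mapping$constants))
    hi <- max(c(fmt$min_fields, match(explicit, bed_fields)), na.rm = TRUE)
    fields <- c(bed_fields[seq_len(hi)],
                if (tail_n) fields[(length(fields) - tail_n + 1L):length(fields)])
    cols <- cols[fields]
  }

  lines <- if (nr) {
    m <- do.call(cbind, cols)
    apply(m, 1L, paste, collapse = "\t")
  } else character(0)
  if (!is.null(track_line)) lines <- c(track_line, lines)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Integer-valued coordinates print without scientific notation or ".0".
format_coord <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}
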