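#' @title Readers: delimited text, VCF and UCSC track formats
#' @description
#' All readers produce a [gtable] with verbatim cells, a provenance label per
#' row (the source file's basename) and, for coordinate-bearing formats, a
#' [location_schema()] so interval operations work immediately.
#' @name readers
NULL

# Read lines from a path or connection. Plain paths and gzip-compressed
# files (".gz") are both accepted; file() auto-detects compression.
read_lines_any <- function(path_or_stream) {
  if (inherits(path_or_stream, "connection"))
    return(readLines(path_or_stream, warn = FALSE))
  if (!is.character(path_or_stream) || length(path_or_stream) != 1L)
    gt_io_error("input must be a single path or a connection")
  if (!file.exists(path_or_stream))
    gt_io_error("cannot read '%s': no such file", path_or_stream)
  tryCatch(readLines(path_or_stream, warn = FALSE),
           error = function(e) gt_io_error("cannot read '%s': %s",
                                           path_or_stream, conditionMessage(e)))
}

source_label_of <- function(path_or_stream, override = NULL) {
  if (!is.null(override)) return(override)
  if (inherits(path_or_stream, "connection")) return("stream")
  basename(path_or_stream)
}

# Split lines into fields. Trailing empty fields are preserved (strsplit
# alone would drop them). With a quote character, fields wrapped in it may
# contain the delimiter; the quotes are stripped.
split_fields <- function(lines, delimiter, quote_char = NULL) {
  if (!length(lines)) return(list())
  if (is.null(quote_char)) {
    parts <- strsplit(paste0(lines, "\x1e"), delimiter, fixed = TRUE)
    lapply(parts, function(p) {
      p[length(p)] <- sub("\x1e$", "", p[length(p)])
      p
    })
  } else {
    lapply(lines, function(ln) {
      scan(text = ln, what = character(), sep = delimiter,
           quote = quote_char, quiet = TRUE, na.strings = character(),
           strip.white = FALSE)
    })
  }
}

num_parses <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read any character-delimited file into a table
#'
#' Comment lines (starting with the dialect's comment character) and blank
#' lines are skipped; the header policy is applied (see [dialect()] for the
#' `"auto"` heuristic); cells equal to the dialect's missing symbol become
#' missing. Cells are otherwise kept verbatim.
#'
#' @param path_or_stream File path (optionally `.gz`) or a text connection.
#' @param dialect A [dialect()].
#' @param source_label Provenance label; defaults to the file's basename.
#' @return A [gtable].
#' @export
read_delimited <- function(path_or_stream, dialect = genotab::dialect(),
                           source_label = NULL) {
  stopifnot(inherits(dialect, "dialect"))
  lines <- read_lines_any(path_or_stream)
  label <- source_label_of(path_or_stream, source_label)
  lineno <- seq_along(lines)
  keep <- nzchar(lines)
  if (!is.null(dialect$comment_char))
    keep <- keep & !startsWith(lines, dialect$comment_char)
  lines <- lines[keep]
  lineno <- lineno[keep]
  fields <- split_fields(lines, dialect$delimiter, dialect$quote_char)

  header_is_first <- switch(dialect$header,
    first_row = TRUE,
    none = FALSE,
    auto = {
      if (length(fields) >= 2L &&
          length(fields[[1L]]) == length(fields[[2L]])) {
        any(!num_parses(fields[[1L]]) & num_parses(fields[[2L]]))
      } else FALSE
    })

  if (header_is_first && length(fields)) {
    names_raw <- fields[[1L]]
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  } else {
    nc <- if (length(fields)) length(fields[[1L]]) else 0L
    names_raw <- auto_name_columns(nc)
  }
  nc <- length(names_raw)
  nf <- lengths(fields)
  bad <- which(nf != nc)
  if (length(bad))
    gt_structural_error("line %d has %d fields, expected %d",
                        lineno[bad[1L]], nf[bad[1L]], nc)

  nr <- length(fields)
  data <- if (nr) {
    m <- matrix(unlist(fields, use.names = FALSE), nrow = nr, ncol = nc,
                byrow = TRUE)
    m[m == dialect$missing_symbol] <- NA_character_
    stats::setNames(lapply(seq_len(nc), function(j) m[, j]),
                    uniquify_names(names_raw))
  } else {
    stats::setNames(rep(list(character(0)), nc), uniquify_names(names_raw))
  }
  new_gtable(data, label)
}

#' Read a VCF file, flattening the INFO field
#'
#' The seven fixed columns (CHROM, POS, ID, REF, ALT, QUAL, FILTER) are kept
#' verbatim. With `expand_info = TRUE` (the default), every key observed in
#' any record's INFO string — whether or not it is declared in a `##INFO`
#' meta line — becomes a column `INFO.<KEY>`: flag keys get `TRUE` where
#' present and missing elsewhere; `key=value` pairs keep the raw value text.
#' With `expand_info = FALSE` the raw INFO column is retained instead.
#' Multi-allelic ALT cells are kept as one comma-joined text cell.
#'
#' The returned table carries a 1-based chrom/pos location schema; interval
#' lengths are taken from REF, so a deletion spans its full reference
#' footprint.
#'
#' @param path_or_stream File path (optionally `.gz`) or a connection.
#' @param expand_info Expand INFO keys into `INFO.<KEY>` columns?
#' @param expand_samples Keep FORMAT and per-sample genotype columns?
#' @param source_label Provenance label; defaults to the file's basename.
#' @return A list with elements `table` (a [gtable]) and `meta` (a `vcf_meta`
#'   with `meta_lines`, `sample_ids`, `declared_info_keys`).
#' @export
read_vcf <- function(path_or_stream, expand_info = TRUE,
                     expand_samples = TRUE, source_label = NULL) {
  lines <- read_lines_any(path_or_stream)
  label <- source_label_of(path_or_stream, source_label)
  is_meta <- startsWith(lines, "##")
  meta_lines <- lines[is_meta]
  rest <- lines[!is_meta]
  restno <- which(!is_meta)
  rest_keep <- nzchar(rest)
  rest <- rest[rest_keep]
  restno <- restno[rest_keep]
  if (!length(rest) || !startsWith(rest[[1L]], "#CHROM"))
    gt_format_error("not a VCF: expected a '#CHROM' header line after the '##' meta lines")
  header <- strsplit(sub("^#", "", rest[[1L]]), "\t", fixed = TRUE)[[1L]]
  sample_ids <- if (length(header) > 9L) header[10:length(header)] else character(0)
  declared <- unique(sub("^##INFO=<ID=([^,>]+).*$", "\\1",
                         grep("^##INFO=<ID=", meta_lines, value = TRUE)))

  body <- rest[-1L]
  bodyno <- restno[-1L]
  fields <- split_fields(body, "\t")
  nf <- lengths(fields)
  bad <- which(nf < 8L)
  if (length(bad))
    gt_structural_error("line %d has %d fields; a VCF record needs at least 8",
                        bodyno[bad[1L]], nf[bad[1L]])

  nr <- length(fields)
  fixed_names <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER")
  get_col <- function(j) vapply(fields, function(f) f[[j]], "")
  data <- stats::setNames(lapply(1:7, function(j) {
    if (nr) get_col(j) else character(0)
  }), fixed_names)

  info_raw <- if (nr) get_col(8L) else character(0)
  if (expand_info) {
    info_cols <- expand_info_strings(info_raw)
    data <- c(data, info_cols)
  } else {
    data$INFO <- info_raw
  }

  if (expand_samples && length(header) >= 9L) {
    extra <- header[9:length(header)]
    for (k in seq_along(extra)) {
      j <- 8L + k
      data[[extra[[k]]]] <- if (nr) {
        vapply(fields, function(f) if (length(f) >= j) f[[j]] else NA_character_, "")
      } else character(0)
    }
  }

  names(data) <- uniquify_names(names(data))
  schema <- location_schema("chrom_pos", c("CHROM", "POS"), "one_closed")
  tab <- new_gtable(data, label, schema = schema)
  meta <- structure(
    list(meta_lines = meta_lines, sample_ids = sample_ids,
         declared_info_keys = declared),
    class = "vcf_meta"
  )
  list(table = tab, meta = meta)
}

# Flatten semicolon-separated key[=value] INFO strings into one column per
# observed key, in order of first observation. "." means no INFO.
expand_info_strings <- function(info_raw) {
  nr <- length(info_raw)
  cols <- list()
  toks <- strsplit(info_raw, ";", fixed = TRUE)
  for (i in seq_len(nr)) {
    for (tok in toks[[i]]) {
      if (tok == "." || tok == "") next
      eq <- regexpr("=", tok, fixed = TRUE)
      if (eq > 0L) {
        key <- substr(tok, 1L, eq - 1L)
        val <- substr(tok, eq + 1L, nchar(tok))
      } else {
        key <- tok
        val <- "TRUE"
      }
      cname <- paste0("INFO.", key)
      if (is.null(cols[[cname]])) cols[[cname]] <- rep(NA_character_, nr)
      cols[[cname]][[i]] <- val
    }
  }
  cols
}

#' List the INFO keys observed in a table read from VCF
#' @param table A [gtable] from [read_vcf()] with `expand_info = TRUE`.
#' @return Character vector of keys (without the `INFO.` prefix).
#' @export
observed_info_keys <- function(table) {
  nms <- grep("^INFO\\.", column_names(table), value = TRUE)
  sub("^INFO\\.", "", nms)
}

track_decl_re <- "^(track|browser)([ \t]|$)"

#' Read a UCSC track file (BED, GFF/GTF, PSL or WIG)
#'
#' `track`/`browser` declaration lines and `#` comments are skipped. BED is
#' parsed tab- or space-delimited with canonical column names and a 0-based
#' half-open schema; GFF/GTF as 9 tab-separated columns with a 1-based
#' closed schema (GTF attributes are not key-expanded); PSL as 21 columns
#' (target coordinates form the schema), with the optional 5-line header
#' skipped; WIG fixedStep/variableStep blocks are expanded to one row per
#' value line with columns (chrom, start, end, value) in 0-based half-open
#' coordinates, honouring `step` and `span`.
#'
#' @param path_or_stream File path (optionally `.gz`) or a connection.
#' @param format_hint One of `"auto"`, `"bed"`, `"gff"`, `"gtf"`, `"psl"`,
#'   `"wig"`. `"auto"` tries WIG, PSL, GFF then BED signatures.
#' @param source_label Provenance label; defaults to the file's basename.
#' @return A [gtable] with the matching location schema.
#' @export
read_track <- function(path_or_stream,
                       format_hint = c("auto", "bed", "gff", "gtf", "psl", "wig"),
                       source_label = NULL) {
  format_hint <- match.arg(format_hint)
  lines <- read_lines_any(path_or_stream)
  label <- source_label_of(path_or_stream, source_label)
  fmt <- if (format_hint == "auto") detect_track_format(lines) else format_hint
  switch(fmt,
    bed = read_bed_lines(lines, label),
    gff = ,
    gtf = read_gff_lines(lines, label),
    psl = read_psl_lines(lines, label),
    wig = read_wig_lines(lines, label))
}

detect_track_format <- function(lines) {
  body <- lines[nzchar(lines) & !grepl(track_decl_re, lines) &
                  !startsWith(lines, "#")]
  if (any(grepl("^(fixedStep|variableStep)[ \t]", lines)))
    return("wig")
  if (length(lines) && grepl("^psLayout", lines[[1L]]))
    return("psl")
  if (length(body)) {
    f <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 21L && all(grepl("^[0-9]+$", f[c(1, 11, 16, 17)])))
      return("psl")
    if (length(f) == 9L && all(grepl("^[0-9]+$", f[4:5])))
      return("gff")
    if (length(f) < 2L) f <- strsplit(body[[1L]], "[ \t]+")[[1L]]
    if (length(f) >= 3L && length(f) <= 12L &&
        all(grepl("^[0-9]+$", f[2:3])))
      return("bed")
  }
  gt_format_error("cannot detect track format (tried wig, psl, gff, bed)")
}

bed_field_names <- c("chrom", "chromStart", "chromEnd", "name", "score",
                     "strand", "thickStart", "thickEnd", "itemRgb",
                     "blockCount", "blockSizes", "blockStarts")

read_bed_lines <- function(lines, label) {
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl(track_decl_re, lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  fields <- lapply(lines, function(ln) {
    if (grepl("\t", ln, fixed = TRUE)) strsplit(ln, "\t", fixed = TRUE)[[1L]]
    else strsplit(ln, " +")[[1L]]
  })
  nf <- lengths(fields)
  if (length(fields)) {
    if (nf[[1L]] < 3L || nf[[1L]] > 12L)
      gt_format_error("line %d: BED needs 3-12 fields, found %d",
                      lineno[[1L]], nf[[1L]])
    bad <- which(nf != nf[[1L]])
    if (length(bad))
      gt_structural_error("line %d has %d fields, expected %d",
                          lineno[bad[1L]], nf[bad[1L]], nf[[1L]])
  }
  nc <- if (length(fields)) nf[[1L]] else 3L
  nms <- bed_field_names[seq_len(nc)]
  data <- stats::setNames(lapply(seq_len(nc), function(j) {
    vapply(fields, `[[`, "", j)
  }), nms)
  schema <- location_schema("three_column", c("chrom", "chromStart", "chromEnd"),
                            "zero_half_open",
                            strand_column = if (nc >= 6L) "strand" else NULL)
  new_gtable(data, label, schema = schema)
}

gff_field_names <- c("seqname", "source", "feature", "start", "end",
                     "score", "strand", "frame", "attribute")

read_gff_lines <- function(lines, label) {
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl(track_decl_re, lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  fields <- split_fields(lines, "\t")
  nf <- lengths(fields)
  bad <- which(nf != 9L)
  if (length(bad))
    gt_structural_error("line %d has %d fields; GFF/GTF needs 9",
                        lineno[bad[1L]], nf[bad[1L]])
  data <- stats::setNames(lapply(1:9, function(j) {
    vapply(fields, `[[`, "", j)
  }), gff_field_names)
  schema <- location_schema("three_column", c("seqname", "start", "end"),
                            "one_closed", strand_column = "strand")
  new_gtable(data, label, schema = schema)
}

psl_field_names <- c("matches", "misMatches", "repMatches", "nCount",
                     "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
                     "strand", "qName", "qSize", "qStart", "qEnd",
                     "tName", "tSize", "tStart", "tEnd",
                     "blockCount", "blockSizes", "qStarts", "tStarts")

read_psl_lines <- function(lines, label) {
  lineno <- seq_along(lines)
  # optional 5-line header: psLayout line, blurb, column names x2, "----"
  if (length(lines) && grepl("^psLayout", lines[[1L]])) {
    dashes <- grep("^-{5,}", lines)
    skip <- if (length(dashes)) dashes[[1L]] else min(5L, length(lines))
    lines <- lines[-seq_len(skip)]
    lineno <- lineno[-seq_len(skip)]
  }
  keep <- nzchar(lines) & !grepl(track_decl_re, lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  fields <- split_fields(lines, "\t")
  nf <- lengths(fields)
  bad <- which(nf != 21L)
  if (length(bad))
    gt_structural_error("line %d has %d fields; PSL needs 21",
                        lineno[bad[1L]], nf[bad[1L]])
  data <- stats::setNames(lapply(1:21, function(j) {
    vapply(fields, `[[`, "", j)
  }), psl_field_names)
  schema <- location_schema("three_column", c("tName", "tStart", "tEnd"),
                            "zero_half_open", strand_column = "strand")
  new_gtable(data, label, schema = schema)
}

# Expand WIG declarations to one row per value line. UCSC WIG starts are
# 1-based; output is canonical 0-based half-open.
read_wig_lines <- function(lines, label) {
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl(track_decl_re, lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  chrom <- character(0); start <- integer(0); end <- integer(0)
  value <- character(0)
  mode <- NULL  # NULL | "fixed" | "variable"
  cur <- list()
  parse_kv <- function(ln) {
    toks <- strsplit(ln, "[ \t]+")[[1L]][-1L]
    kv <- strsplit(toks, "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "fixedStep")) {
      kv <- parse_kv(ln)
      if (!all(c("chrom", "start") %in% names(kv)))
        gt_structural_error("line %d: fixedStep needs chrom= and start=", lineno[[i]])
      cur <- list(chrom = kv[["chrom"]],
                  next_start = as.integer(kv[["start"]]),
                  step = as.integer(kv["step"] %na% "1"),
                  span = as.integer(kv["span"] %na% "1"))
      mode <- "fixed"
    } else if (startsWith(ln, "variableStep")) {
      kv <- parse_kv(ln)
      if (!"chrom" %in% names(kv))
        gt_structural_error("line %d: variableStep needs chrom=", lineno[[i]])
      cur <- list(chrom = kv[["chrom"]],
                  span = as.integer(kv["span"] %na% "1"))
      mode <- "variable"
    } else if (is.null(mode)) {
      gt_structural_error("line %d: WIG data line outside any fixedStep/variableStep declaration",
                          lineno[[i]])
    } else if (mode == "fixed") {
      s0 <- cur$next_start - 1L
      chrom <- c(chrom, cur$chrom)
      start <- c(start, s0)
      end <- c(end, s0 + cur$span)
      value <- c(value, trimws(ln))
      cur$next_start <- cur$next_start + cur$step
    } else {
      toks <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      if (length(toks) != 2L)
        gt_structural_error("line %d: variableStep data line needs 'position value'",
                            lineno[[i]])
      s0 <- as.integer(toks[[1L]]) - 1L
      chrom <- c(chrom, cur$chrom)
      start <- c(start, s0)
      end <- c(end, s0 + cur$span)
      value <- c(value, toks[[2L]])
    }
  }
  data <- list(chrom = chrom, start = as.character(start),
               end = as.character(end), value = value)
  schema <- location_schema("three_column", c("chrom", "start", "end"),
                            "zero_half_open")
  new_gtable(data, label, schema = schema)
}

# value-or-default for possibly-absent named vector entries
`%na%` <- function(x, default) {
  x <- unname(x)
  if (length(x) != 1L || is.na(x)) default else x
}

#' Open several files, each with its own dialect
#'
#' Each file becomes its own table with its basename as provenance label;
#' no combining is performed (use the merge operations for that). All paths
#' are checked before any file is parsed, so a bad path never leaves part of
#' the set silently processed.
#'
#' @param paths Character vector of file paths (at least one).
#' @param dialects A single [dialect()] applied to all files, a list of
#'   dialects (one per path), or `NULL` for the default dialect.
#' @return A list of [gtable]s, one per path.
#' @export
open_many <- function(paths, dialects = NULL) {
  if (!length(paths)) gt_io_error("no input files")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    gt_io_error("cannot read '%s': no such file", missing[[1L]])
  if (is.null(dialects)) dialects <- dialect()
  if (inherits(dialects, "dialect"))
    dialects <- rep(list(dialects), length(paths))
  if (length(dialects) != length(paths))
    gt_spec_error("need one dialect per path (%d paths, %d dialects)",
                  length(paths), length(dialects))
  Map(function(p, d) read_delimited(p, d), paths, dialects)
}
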