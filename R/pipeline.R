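#' Convert one file between formats
#'
#' Reads the input with the appropriate reader, then writes it in the
#' requested output format. Row and column counts are logged to standard
#' error.
#'
#' @param input Input file path.
#' @param output Output file path.
#' @param in_format `"auto"`, `"delimited"`, `"vcf"`, `"bed"`, `"gff"`,
#'   `"gtf"`, `"psl"` or `"wig"`. `"auto"` uses the file suffix, falling
#'   back to track auto-detection, then delimited.
#' @param out_format `"tab"` or any [column_mapping()] format name.
#' @param dialect A [dialect()] for delimited input.
#' @param mapping Optional [column_mapping()]; defaults to an unbound
#'   mapping for `out_format`.
#' @param track_line Optional track declaration line for track output.
#' @return Invisibly, the output table that was written.
#' @export
run_convert <- function(input, output, in_format = "auto", out_format = "tab",
                        dialect = genotab::dialect(), mapping = NULL,
                        track_line = NULL) {
  tab <- read_any(input, in_format, dialect)
  message(sprintf("read %s: %d rows, %d columns", input, n_rows(tab),
                  length(column_names(tab))))
  if (out_format == "tab") {
    export_tab(tab, output)
  } else {
    mapping <- mapping %||% column_mapping(out_format)
    export_track(tab, mapping, output, track_line = track_line)
  }
  message(sprintf("wrote %s: %d rows (%s)", output, n_rows(tab), out_format))
  invisible(tab)
}

read_any <- function(path, in_format = "auto", dialect = genotab::dialect()) {
  if (in_format == "auto") in_format <- guess_format(path)
  switch(in_format,
    vcf = read_vcf(path)$table,
    bed = , gff = , gtf = , psl = , wig = read_track(path, in_format),
    delimited = read_delimited(path, dialect),
    gt_spec_error("unknown input format '%s'", in_format))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("vcf")) return("vcf")
  if (ext %in% c("bed", "gff", "gff3", "gtf", "psl", "wig"))
    return(sub("gff3", "gff", ext))
  fmt <- tryCatch(detect_track_format(read_lines_any(path)),
                  genotab_format_error = function(e) NULL)
  fmt %||% "delimited"
}

# ---- YAML pipeline ---------------------------------------------------------

#' Run a configured pipeline
#'
#' The configuration (YAML file or an equivalent R list) declares `inputs`
#' (alias, path, format, dialect options), an ordered list of `steps`
#' (merge, append, filter, list_filter, criteria, samples, select, dedupe),
#' and an `output` (input alias, path, format, optional mapping and track
#' line). Steps read and write tables by alias. A step may instead be
#' `include: path`, splicing in the steps of another YAML file, so itemized
#' sets of conditions can be shared between pipelines.
#'
#' The whole configuration is validated before any data is read, and every
#' problem is reported at once. The output file is written atomically
#' (temp file then rename), so a failing run never leaves a partial output.
#' Per-step row counts are logged to standard error.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Invisibly, the final output table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) gt_io_error("cannot read '%s': no such file", config)
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  } else base_dir <- "."
  config$steps <- splice_includes(config$steps %||% list(), base_dir)
  problems <- validate_pipeline(config)
  if (length(problems))
    gt_validation_error("invalid pipeline configuration:\n%s",
                        paste0("  - ", problems, collapse = "\n"))

  env <- new.env(parent = emptyenv())
  for (inp in config$inputs) {
    d <- dialect(delimiter = inp$delimiter %||% "\t",
                 comment_char = inp$comment_char,
                 missing_symbol = inp$missing_symbol %||% "",
                 header = inp$header %||% "auto")
    path <- resolve_path(inp$path, base_dir)
    tab <- read_any(path, inp$format %||% "auto", d)
    message(sprintf("input %s (%s): %d rows", inp$alias, basename(path),
                    n_rows(tab)))
    assign(inp$alias, tab, envir = env)
  }

  for (i in seq_along(config$steps)) {
    step <- config$steps[[i]]
    res <- tryCatch(run_step(step, env, base_dir),
                    genotab_error = function(e) {
                      gt_stop(class(e)[[1L]],
                              "step %d (%s): %s", i, step$op,
                              conditionMessage(e))
                    })
    out_alias <- step$result %||% step$input
    n_in <- if (!is.null(step$input) && exists(step$input, envir = env))
      n_rows(get(step$input, envir = env)) else NA_integer_
    message(sprintf("step %d (%s): rows in %s -> rows out %d",
                    i, step$op, ifelse(is.na(n_in), "?", n_in), n_rows(res)))
    assign(out_alias, res, envir = env)
  }

  out <- config$output
  tab <- get(out$input, envir = env)
  path <- resolve_path(out$path, base_dir)
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(unlink(tmp), add = TRUE)
  fmtname <- out$format %||% "tab"
  if (fmtname == "tab") {
    export_tab(tab, tmp, write_header = out$write_header %||% TRUE,
               missing_symbol = out$missing_symbol %||% "")
  } else {
    mapping <- column_mapping(
      fmtname,
      bindings = unlist(out$bindings %||% list()),
      constants = unlist(out$constants %||% list()))
    export_track(tab, mapping, tmp, track_line = out$track_line)
  }
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  message(sprintf("output %s: %d rows (%s)", path, n_rows(tab), fmtname))
  invisible(tab)
}

resolve_path <- function(path, base_dir) {
  if (grepl("^([A-Za-z]:)?[/\\\\]", path)) path else file.path(base_dir, path)
}

splice_includes <- function(steps, base_dir) {
  out <- list()
  for (step in steps) {
    if (!is.null(step$include)) {
      path <- resolve_path(step$include, base_dir)
      if (!file.exists(path))
        gt_io_error("cannot read included steps '%s': no such file", path)
      out <- c(out, splice_includes(yaml::read_yaml(path), dirname(path)))
    } else {
      out <- c(out, list(step))
    }
  }
  out
}

pipeline_ops <- c("merge", "append", "filter", "list_filter", "criteria",
                  "samples", "select", "dedupe")

# Validate aliases, ops and required parameters without touching any data;
# returns a character vector of ALL problems found.
validate_pipeline <- function(config) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))
  inputs <- config$inputs %||% list()
  if (!length(inputs)) note("no inputs declared")
  defined <- character(0)
  for (k in seq_along(inputs)) {
    inp <- inputs[[k]]
    if (is.null(inp$alias)) note("input %d has no alias", k)
    else defined <- c(defined, inp$alias)
    if (is.null(inp$path)) note("input %d (%s) has no path", k,
                                inp$alias %||% "?")
  }
  for (i in seq_along(config$steps)) {
    step <- config$steps[[i]]
    op <- step$op %||% ""
    if (!op %in% pipeline_ops) {
      note("step %d: unknown op '%s'", i, op)
      next
    }
    refs <- switch(op,
      merge = c(step$left, step$right),
      append = unlist(step$inputs),
      c(step$input))
    if (!length(refs) || is.null(refs))
      note("step %d (%s): no input alias given", i, op)
    for (r in refs) if (!r %in% defined)
      note("step %d (%s): undefined alias '%s'", i, op, r)
    if (op == "merge" && is.null(step$by) && is.null(step$keys))
      note("step %d (merge): needs by: location or keys: [...]", i)
    if (op == "criteria" && is.null(step$criteria))
      note("step %d (criteria): needs a criteria: alias", i)
    if (op == "criteria" && !is.null(step$criteria) &&
        !step$criteria %in% defined)
      note("step %d (criteria): undefined alias '%s'", i, step$criteria)
    if (op == "filter" && is.null(step$predicates))
      note("step %d (filter): needs predicates:", i)
    if (op == "list_filter" && (is.null(step$column) || is.null(step$list)))
      note("step %d (list_filter): needs column: and list:", i)
    if (op == "samples" && is.null(step$sample_columns))
      note("step %d (samples): needs sample_columns:", i)
    if (op == "select" && is.null(step$columns))
      note("step %d (select): needs columns:", i)
    defined <- c(defined, step$result %||% step$input)
  }
  out <- config$output
  if (is.null(out)) note("no output declared")
  else {
    if (is.null(out$path)) note("output has no path")
    if (is.null(out$input)) note("output names no input alias")
    else if (!out$input %in% defined)
      note("output: undefined alias '%s'", out$input)
  }
  problems
}

parse_config_predicate <- function(p) {
  predicate(p$column, p$op %||% "eq",
            operand = p$value %||% p$values,
            on_missing = p$on_missing %||% "drop")
}

run_step <- function(step, env, base_dir) {
  tab_of <- function(alias) get(alias, envir = env)
  switch(step$op,
    merge = {
      keys <- step$keys
      if (!is.null(keys)) {
        kv <- vapply(keys, function(k) {
          if (is.list(k)) as.character(k$right %||% k[[2L]])
          else as.character(k)
        }, "")
        names(kv) <- vapply(keys, function(k) {
          if (is.list(k)) as.character(k$left %||% k[[1L]])
          else as.character(k)
        }, "")
        spec <- join_spec(mode = step$mode %||% "inner",
                          predicate = "key_equality", key_columns = kv,
                          multiplicity = step$multiplicity %||% "expand_pairs")
        merge_by_keys(tab_of(step$left), tab_of(step$right), spec)
      } else {
        spec <- join_spec(mode = step$mode %||% "inner",
                          predicate = step$predicate %||% "overlap",
                          min_fraction = step$min_fraction %||% 0,
                          multiplicity = step$multiplicity %||% "expand_pairs")
        merge_by_location(tab_of(step$left), tab_of(step$right), spec)
      }
    },
    append = append_tables(lapply(unlist(step$inputs), tab_of)),
    filter = {
      preds <- lapply(step$predicates, parse_config_predicate)
      filter_rows(tab_of(step$input), preds, combine = step$combine %||% "all")
    },
    list_filter = {
      lp <- step$list
      if (length(lp) == 1L && is.character(lp) && !is.null(step$list_is_path)
          || (length(lp) == 1L && file.exists(resolve_path(lp, base_dir))))
        lp <- resolve_path(lp, base_dir)
      filter_by_list(tab_of(step$input), step$column, lp,
                     negate = isTRUE(step$negate))
    },
    criteria = {
      pred <- if (!is.null(step$criteria_predicate))
        parse_config_predicate(step$criteria_predicate)
      spec <- criteria_spec(tab_of(step$criteria),
                            polarity = step$polarity %||% "keep_overlapping",
                            min_fraction = step$min_fraction %||% 0,
                            criteria_predicate = pred)
      filter_by_criteria(tab_of(step$input), spec)
    },
    samples = {
      spec <- sample_spec(unlist(step$sample_columns),
                          identity_columns = unlist(step$identity_columns),
                          threshold = step$threshold %||% 0.5,
                          direction = step$direction %||% "at_least",
                          total_samples = step$total_samples)
      filter_by_sample_presence(tab_of(step$input), spec)
    },
    select = select_columns(tab_of(step$input), unlist(step$columns)),
    dedupe = deduplicate(tab_of(step$input), unlist(step$key_columns)))
}
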