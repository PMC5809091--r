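# Classed conditions so callers (and the CLI) can distinguish user mistakes
# from data problems. All inherit from "genotab_error".

gt_stop <- function(class, msg, ..., call = sys.call(-1)) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "genotab_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

gt_structural_error <- function(msg, ...) gt_stop("genotab_structural_error", msg, ...)
gt_format_error     <- function(msg, ...) gt_stop("genotab_format_error", msg, ...)
gt_io_error         <- function(msg, ...) gt_stop("genotab_io_error", msg, ...)
gt_schema_error     <- function(msg, ...) gt_stop("genotab_schema_error", msg, ...)
gt_spec_error       <- function(msg, ...) gt_stop("genotab_spec_error", msg, ...)
gt_type_error       <- function(msg, ...) gt_stop("genotab_type_error", msg, ...)
gt_data_error       <- function(msg, ...) gt_stop("genotab_data_error", msg, ...)
gt_export_error     <- function(msg, ...) gt_stop("genotab_export_error", msg, ...)
gt_validation_error <- function(msg, ...) gt_stop("genotab_validation_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
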