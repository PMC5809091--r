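# Shared builders for in-memory tables and brute-force oracles.

# A gtable of random intervals with a three-column 0-based half-open schema.
random_interval_table <- function(n, chroms = c("chr1", "chr2", "chr3"),
                                  max_pos = 10000L, max_len = 500L,
                                  label = "rand") {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tab <- make_table(c("chrom", "start", "end", "id"),
                    lapply(seq_len(n), function(i) {
                      c(chrom[i], start[i], start[i] + len[i], paste0("r", i))
                    }), label)
  set_location_schema(tab, location_schema("three_column",
                                           c("chrom", "start", "end"),
                                           "zero_half_open"))
}

# Exhaustive all-pairs scan with the scalar overlap predicate: the oracle
# the interval index and the location join are checked against.
brute_force_pairs <- function(li, ri, min_fraction = 0) {
  out_l <- integer(0); out_r <- integer(0)
  for (i in seq_len(nrow(li))) {
    for (j in seq_len(nrow(ri))) {
      if (interval_overlaps(li[i, ], ri[j, ], min_fraction)) {
        out_l <- c(out_l, i); out_r <- c(out_r, j)
      }
    }
  }
  data.frame(left = out_l, right = out_r)
}

pair_set <- function(df, a = 1L, b = 2L) {
  sort(paste(df[[a]], df[[b]], sep = "/"))
}

# Explicit double-loop recomputation of the sample-presence filter,
# independent of the grouped implementation.
sample_presence_oracle <- function(table, sample_cols, id_cols, threshold,
                                   direction = "at_least",
                                   total_override = NULL) {
  n <- n_rows(table)
  skey <- apply(do.call(cbind, lapply(sample_cols, column_values, x = table)),
                1, paste, collapse = "|")
  smiss <- Reduce(`|`, lapply(sample_cols,
                              function(cn) is.na(column_values(table, cn))))
  ikey <- apply(do.call(cbind, lapply(id_cols, function(cn) {
    v <- column_values(table, cn); ifelse(is.na(v), "<NA>", v)
  })), 1, paste, collapse = "|")
  total <- total_override
  if (is.null(total)) total <- length(unique(skey[!smiss]))
  keep <- logical(n)
  for (i in seq_len(n)) {
    seen <- character(0)
    for (j in seq_len(n)) {
      if (ikey[j] == ikey[i] && !smiss[j]) seen <- union(seen, skey[j])
    }
    frac <- length(seen) / total
    keep[i] <- if (direction == "at_least") frac >= threshold
               else frac <= threshold
  }
  which(keep)
}

# Write lines and return the path (LF, no trailing-newline surprises).
write_fixture <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}
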