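#' @title Deterministic synthetic input generators
#' @description
#' Generators for the file types the engine consumes — VCF with canonical
#' and non-canonical INFO keys, conservation-style score tracks (BED, GFF or
#' WIG) and multi-sample variant tables. Every generator is seeded and emits
#' machine-readable ground truth alongside the file, so tests never derive
#' expectations from the parser under test. The same seed always produces
#' byte-identical files.
#' @name fixtures
NULL

#' Parameters for the synthetic generators
#'
#' @param seed RNG seed; the same seed gives byte-identical output.
#' @param n_variants Number of VCF records / loci.
#' @param n_samples Number of samples.
#' @param n_criteria_intervals Number of intervals in a criteria track.
#' @param chroms Chromosome names to draw from.
#' @param region_length Length of the simulated region on each chromosome;
#'   variant positions and criteria intervals are both drawn inside it, so
#'   criteria filtering has realistic overlap rates.
#' @param declared_info_keys INFO keys declared in `##INFO` meta lines.
#' @param extra_info_keys INFO keys used in records but never declared
#'   (non-canonical entries).
#' @param fraction_conserved Fraction of track intervals given a score
#'   above 0.85 (the conserved set); the count is exact:
#'   `round(fraction_conserved * n_criteria_intervals)`.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_variants = 50L, n_samples = 3L,
                         n_criteria_intervals = 100L,
                         chroms = c("chr1", "chr2", "chr3"),
                         region_length = 20000L,
                         declared_info_keys = c("DP", "AF"),
                         extra_info_keys = c("MYCALLER_SCORE", "NOVEL"),
                         fraction_conserved = 0.3) {
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 n_samples = as.integer(n_samples),
                 n_criteria_intervals = as.integer(n_criteria_intervals),
                 chroms = chroms, region_length = as.integer(region_length),
                 declared_info_keys = declared_info_keys,
                 extra_info_keys = extra_info_keys,
                 fraction_conserved = fraction_conserved),
            class = "fixture_spec")
}

# run code under a local, restored RNG state
with_fixture_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

write_text <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

maybe_sidecar <- function(truth, path) {
  if (!is.null(path))
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(truth)
}

#' Generate a VCF file with known INFO content
#'
#' Declared keys get `##INFO` meta lines; extra keys appear in records
#' undeclared (non-canonical). One extra key is a flag (present without a
#' value on a subset of records), value-bearing keys appear on a random
#' subset of records. Ground truth lists every record and its expanded
#' key/value map.
#'
#' @param spec A [fixture_spec()].
#' @param path Output VCF path.
#' @param ground_truth_path Optional path for a JSON sidecar of the ground
#'   truth.
#' @return Invisibly, the ground truth: a list with `records` (one entry
#'   per record: chrom, pos, id, ref, alt and the expanded info map) and
#'   `info_keys` (every key any record carries).
#' @export
make_vcf_fixture <- function(spec, path, ground_truth_path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, {
    n <- spec$n_variants
    bases <- c("A", "C", "G", "T")
    chrom <- sort(sample(spec$chroms, n, replace = TRUE))
    pos <- integer(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(spec$region_length, length(idx)))
    }
    ref_len <- sample(c(1L, 1L, 1L, 2L, 3L), n, replace = TRUE)
    ref <- vapply(ref_len, function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), "")
    alt <- vapply(seq_len(n), function(i) {
      a <- sample(setdiff(bases, substr(ref[[i]], 1L, 1L)), 1L)
      if (stats::runif(1) < 0.1) paste(a, sample(bases, 1L), sep = ",") else a
    }, "")
    qual <- sprintf("%.1f", stats::runif(n, 10, 99))
    filter <- sample(c("PASS", "q10"), n, replace = TRUE, prob = c(0.8, 0.2))

    flag_key <- spec$extra_info_keys[[length(spec$extra_info_keys)]]
    value_extras <- setdiff(spec$extra_info_keys, flag_key)
    records <- vector("list", n)
    info_str <- character(n)
    for (i in seq_len(n)) {
      info <- list()
      for (k in spec$declared_info_keys) {
        info[[k]] <- switch(k,
          DP = as.character(sample.int(100L, 1L)),
          AF = sprintf("%.3f", stats::runif(1)),
          as.character(sample.int(50L, 1L)))
      }
      for (k in value_extras) {
        if (stats::runif(1) < 0.5) info[[k]] <- sprintf("%.2f", stats::runif(1))
      }
      if (stats::runif(1) < 0.4) info[[flag_key]] <- "TRUE"
      parts <- vapply(names(info), function(k) {
        if (identical(info[[k]], "TRUE") && k == flag_key) k
        else paste0(k, "=", info[[k]])
      }, "")
      info_str[[i]] <- if (length(parts)) paste(parts, collapse = ";") else "."
      records[[i]] <- list(chrom = chrom[[i]], pos = pos[[i]],
                           id = paste0("var", i), ref = ref[[i]],
                           alt = alt[[i]], info = info)
    }

    gts <- if (spec$n_samples > 0L) {
      matrix(sample(c("0/0", "0/1", "1/1"), n * spec$n_samples,
                    replace = TRUE), nrow = n)
    } else NULL
    sample_ids <- if (spec$n_samples > 0L)
      paste0("S", seq_len(spec$n_samples)) else character(0)

    meta <- c("##fileformat=VCFv4.2",
              sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
                      spec$declared_info_keys, spec$declared_info_keys))
    header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO",
                      if (length(sample_ids)) c("FORMAT", sample_ids)),
                    collapse = "\t")
    body <- vapply(seq_len(n), function(i) {
      paste(c(chrom[[i]], pos[[i]], paste0("var", i), ref[[i]], alt[[i]],
              qual[[i]], filter[[i]], info_str[[i]],
              if (length(sample_ids)) c("GT", gts[i, ])),
            collapse = "\t")
    }, "")
    write_text(c(meta, header, body), path)

    truth <- list(
      records = records,
      info_keys = unique(unlist(lapply(records, function(r) names(r$info)))),
      sample_ids = sample_ids)
    maybe_sidecar(truth, ground_truth_path)
    invisible(truth)
  })
}

#' Generate a scored criteria track (BED, GFF or WIG)
#'
#' Non-overlapping intervals per chromosome with a conservation-style score
#' in [0, 1]; exactly `round(fraction_conserved * n)` of them score above
#' 0.85. Ground truth lists every interval in canonical 0-based half-open
#' coordinates with its score and conserved flag.
#'
#' @param spec A [fixture_spec()].
#' @param format `"bed"`, `"gff"` or `"wig"`.
#' @param path Output file path.
#' @param ground_truth_path Optional JSON sidecar path.
#' @return Invisibly, the ground truth data frame
#'   (`chrom`, `start`, `end`, `score`, `conserved`).
#' @export
make_track_fixture <- function(spec, format = c("bed", "gff", "wig"), path,
                               ground_truth_path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  format <- match.arg(format)
  with_fixture_seed(spec$seed + 1L, {
    n <- spec$n_criteria_intervals
    chrom <- sort(sample(spec$chroms, n, replace = TRUE))
    width <- if (format == "wig") {
      rep(sample.int(20L, 1L), n)  # one span for the whole track
    } else sample(50:500, n, replace = TRUE)
    start <- integer(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      gaps <- sample(10:200, length(idx), replace = TRUE)
      start[idx] <- cumsum(gaps + width[idx]) - width[idx]
    }
    end <- start + width
    n_cons <- round(spec$fraction_conserved * n)
    conserved <- seq_len(n) %in% sample.int(n, n_cons)
    score <- numeric(n)
    score[conserved] <- stats::runif(sum(conserved), 0.851, 0.999)
    score[!conserved] <- stats::runif(sum(!conserved), 0, 0.849)
    score <- round(score, 3)

    lines <- switch(format,
      bed = sprintf("%s\t%d\t%d\tiv%d\t%s\t+", chrom, start, end,
                    seq_len(n), format_coord(score)),
      gff = sprintf("%s\tsynth\tregion\t%d\t%d\t%s\t+\t.\tiv%d",
                    chrom, start + 1L, end, format_coord(score), seq_len(n)),
      wig = {
        out <- character(0)
        span <- width[[1L]]
        for (ch in unique(chrom)) {
          idx <- which(chrom == ch)
          for (i in idx) {
            # one variableStep block per chromosome keeps 1 row per value
            if (i == idx[[1L]])
              out <- c(out, sprintf("variableStep chrom=%s span=%d", ch, span))
            out <- c(out, sprintf("%d %s", start[[i]] + 1L,
                                  format_coord(score[[i]])))
          }
        }
        out
      })
    write_text(lines, path)
    truth <- data.frame(chrom = chrom, start = start, end = end,
                        score = score, conserved = conserved,
                        stringsAsFactors = FALSE)
    maybe_sidecar(truth, ground_truth_path)
    invisible(truth)
  })
}

#' Generate a multi-sample variant table with known presence fractions
#'
#' Rows are (chrom, pos, sample, genotype); each locus is present in a
#' random non-empty subset of the samples, and every sample is guaranteed
#' to be observed. Ground truth maps each locus to its presence fraction
#' (distinct samples carrying it / samples observed in the file).
#'
#' @param spec A [fixture_spec()].
#' @param path Output tab-delimited path.
#' @param ground_truth_path Optional JSON sidecar path.
#' @return Invisibly, the ground truth: list with `total_samples` and
#'   `presence` (named numeric vector keyed by `"chrom:pos"`).
#' @export
make_multisample_fixture <- function(spec, path, ground_truth_path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed + 2L, {
    n <- spec$n_variants
    m <- spec$n_samples
    samples <- paste0("S", seq_len(m))
    chrom <- sample(spec$chroms, n, replace = TRUE)
    pos <- sample.int(spec$region_length, n)
    rows <- list()
    carriers <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sample.int(m, 1L)
      who <- if (i <= m) {
        # first m loci pin one sample each so every sample is observed
        unique(c(samples[[i]], sample(samples, k)))
      } else sample(samples, k)
      carriers[[i]] <- sort(who)
      for (s in sort(who)) {
        rows[[length(rows) + 1L]] <-
          c(chrom[[i]], as.character(pos[[i]]), s,
            sample(c("0/1", "1/1"), 1L))
      }
    }
    header <- "chrom\tpos\tsample\tgenotype"
    body <- vapply(rows, paste, "", collapse = "\t")
    write_text(c(header, body), path)
    presence <- stats::setNames(
      vapply(carriers, function(w) length(w) / m, 0),
      paste0(chrom, ":", pos))
    truth <- list(total_samples = m, presence = as.list(presence))
    maybe_sidecar(truth, ground_truth_path)
    invisible(list(total_samples = m, presence = presence))
  })
}
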