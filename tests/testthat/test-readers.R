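test_that("read_delimited applies dialect: comments, header, missing symbol", {
  p <- write_fixture(c("a\tb", "1\tx", "2\ty"))
  t <- read_delimited(p, dialect(header = "first_row"))
  expect_equal(n_rows(t), 2L)
  expect_identical(column_names(t), c("a", "b"))

  p2 <- write_fixture(c("#note", "a\tb", "1\tx", "2\ty"))
  t2 <- read_delimited(p2, dialect(comment_char = "#", header = "first_row"))
  expect_identical(t2$data, t$data)

  p3 <- write_fixture(c("1\t.", "2\t5"))
  t3 <- read_delimited(p3, dialect(missing_symbol = ".", header = "none"))
  expect_identical(column_values(t3, "col_2"), c(NA, "5"))
})

test_that("header auto-detection promotes a header only when row 1 is non-numeric above numbers", {
  with_header <- read_delimited(write_fixture(c("name\tscore", "x\t1", "y\t2")))
  expect_identical(column_names(with_header), c("name", "score"))
  expect_equal(n_rows(with_header), 2L)

  no_header <- read_delimited(write_fixture(c("x\ta", "y\tb")))
  expect_identical(column_names(no_header), c("col_1", "col_2"))
  expect_equal(n_rows(no_header), 2L)

  single_row <- read_delimited(write_fixture("x\t1"))
  expect_equal(n_rows(single_row), 1L)
})

test_that("field-count mismatches are structural errors naming the line", {
  p <- write_fixture(c("a\tb", "1\tx", "2"))
  expect_error(read_delimited(p, dialect(header = "first_row")),
               regexp = "line 3", class = "genotab_structural_error")
  expect_error(read_delimited(tempfile("absent")),
               class = "genotab_io_error")
})

test_that("alternative delimiters, quotes and gzip input are honoured", {
  p <- write_fixture(c("a,b", "1,\"x,y\""), ext = ".csv")
  t <- read_delimited(p, dialect(delimiter = ",", quote_char = "\"",
                                 header = "first_row"))
  expect_identical(column_values(t, "b"), "x,y")

  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "wb")
  writeLines(c("a\tb", "1\tx"), con)
  close(con)
  tg <- read_delimited(gz, dialect(header = "first_row"))
  expect_identical(column_values(tg, "b"), "x")
})

vcf_lines <- function(records,
                      info_meta = "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
                      samples = character(0)) {
  hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", if (length(samples)) c("FORMAT", samples)),
               collapse = "\t")
  c("##fileformat=VCFv4.2", info_meta, hdr, records)
}

test_that("read_vcf expands declared, undeclared and flag INFO keys", {
  p <- write_fixture(vcf_lines(c(
    "chr1\t10\tv1\tA\tC\t50\tPASS\tDP=10;NOVEL",
    "chr1\t20\tv2\tG\tT\t60\tPASS\tDP=7;MYCALLER_SCORE=0.3")))
  res <- read_vcf(p)
  t <- res$table
  expect_identical(column_values(t, "INFO.DP"), c("10", "7"))
  expect_identical(column_values(t, "INFO.NOVEL"), c("TRUE", NA))
  # non-canonical key, absent from ##INFO meta lines, still expands
  expect_identical(column_values(t, "INFO.MYCALLER_SCORE"), c(NA, "0.3"))
  expect_identical(res$meta$declared_info_keys, "DP")
  expect_identical(res$meta$sample_ids, character(0))
  expect_equal(column_types(t)[["INFO.NOVEL"]], "flag")
})

test_that("read_vcf keeps fixed fields verbatim and handles samples / sites-only", {
  p <- write_fixture(vcf_lines(
    "chr1\t10\tv1\tA\tC,G\t50\tPASS\tDP=10\tGT\t0/1\t1/1",
    samples = c("S1", "S2")))
  res <- read_vcf(p)
  expect_identical(column_values(res$table, "ALT"), "C,G")  # no allele split
  expect_identical(column_values(res$table, "S2"), "1/1")
  expect_identical(res$meta$sample_ids, c("S1", "S2"))
  res2 <- read_vcf(p, expand_samples = FALSE)
  expect_false("S1" %in% column_names(res2$table))
  res3 <- read_vcf(p, expand_info = FALSE)
  expect_identical(column_values(res3$table, "INFO"), "DP=10")

  expect_error(read_vcf(write_fixture(c("##meta", "chr1\t1"))),
               class = "genotab_format_error")
  expect_error(read_vcf(write_fixture(vcf_lines("chr1\t10\tv1\tA"))),
               regexp = "line 4", class = "genotab_structural_error")
})

test_that("INFO expansion recovers exactly the keys present in the raw strings", {
  set.seed(9)
  keys <- c("DP", "AF", "NOVEL", "XX_SCORE")
  n <- 40
  raw <- vapply(seq_len(n), function(i) {
    use <- keys[runif(4) < 0.5]
    if (!length(use)) return(".")
    paste(vapply(use, function(k) {
      if (k == "NOVEL") k else paste0(k, "=", sample.int(100, 1))
    }, ""), collapse = ";")
  }, "")
  recs <- sprintf("chr1\t%d\tv%d\tA\tC\t50\tPASS\t%s", seq_len(n) * 10,
                  seq_len(n), raw)
  res <- read_vcf(write_fixture(vcf_lines(recs)))
  # independent oracle: scan the raw INFO strings directly
  expected <- unique(unlist(lapply(strsplit(raw[raw != "."], ";"),
                                   function(t) sub("=.*$", "", t))))
  expect_setequal(observed_info_keys(res$table), expected)
  for (k in expected) {
    has_key <- grepl(paste0("(^|;)", k, "(=|;|$)"), raw)
    expect_identical(!is.na(column_values(res$table, paste0("INFO.", k))),
                     has_key)
  }
})

test_that("read_track parses BED with canonical names and 0-based schema", {
  t <- read_track(write_fixture(c("track name=demo", "browser position chr1",
                                  "chr1\t100\t200\tfeat\t0\t+")), "bed")
  expect_equal(n_rows(t), 1L)
  expect_identical(column_values(t, "chromStart"), "100")
  iv <- extract_intervals(t)
  expect_equal(iv$start, 100)
  expect_equal(iv$end, 200)
  expect_equal(iv$strand, "+")
  # space-delimited BED is accepted too
  ts <- read_track(write_fixture("chr1 5 9"), "bed")
  expect_equal(extract_intervals(ts)$start, 5)
})

test_that("read_track parses GFF with 1-based closed convention", {
  t <- read_track(write_fixture("chr1\tsrc\tgene\t101\t200\t.\t+\t.\tg1"), "gff")
  expect_identical(column_values(t, "start"), "101")  # verbatim
  iv <- extract_intervals(t)
  expect_equal(iv$start, 100)  # canonical
  expect_equal(iv$end, 200)
  expect_error(read_track(write_fixture("chr1\tsrc\tgene\t101"), "gff"),
               class = "genotab_structural_error")
})

test_that("read_track parses PSL (21 columns, optional header skipped)", {
  row <- paste(c(50, 0, 0, 0, 0, 0, 0, 0, "+", "q1", 50, 0, 50,
                 "chr1", 1000, 100, 150, 1, "50,", "0,", "100,"),
               collapse = "\t")
  hdr <- c("psLayout version 3", "", "match\tmis-", "     \t    ",
           "---------------------------------")
  t <- read_track(write_fixture(c(hdr, row)), "psl")
  expect_equal(n_rows(t), 1L)
  expect_identical(column_values(t, "tName"), "chr1")
  iv <- extract_intervals(t)
  expect_equal(iv$start, 100)
  expect_equal(iv$end, 150)
})

test_that("WIG fixedStep and variableStep expand with step and span arithmetic", {
  t <- read_track(write_fixture(c(
    "track type=wiggle_0",
    "fixedStep chrom=chr1 start=101 step=10 span=5",
    "1.0", "2.0")), "wig")
  iv <- extract_intervals(t)
  expect_equal(iv$start, c(100, 110))
  expect_equal(iv$end, c(105, 115))
  expect_identical(column_values(t, "value"), c("1.0", "2.0"))

  tv <- read_track(write_fixture(c(
    "variableStep chrom=chrX span=3", "11 0.5", "31 0.7")), "wig")
  ivv <- extract_intervals(tv)
  expect_equal(ivv$start, c(10, 30))
  expect_equal(ivv$end, c(13, 33))

  # row count equals value-line count; defaults step=1 span=1
  td <- read_track(write_fixture(c("fixedStep chrom=chr2 start=1",
                                   as.character(1:7))), "wig")
  expect_equal(n_rows(td), 7L)
  expect_error(read_track(write_fixture(c("0.5", "fixedStep chrom=chr1 start=1")),
                          "wig"),
               class = "genotab_structural_error")
})

test_that("track format auto-detection distinguishes the four formats", {
  expect_equal(n_rows(read_track(write_fixture("chr1\t1\t2"))), 1L)
  g <- read_track(write_fixture("chr1\ts\tf\t1\t2\t.\t+\t.\tx"))
  expect_identical(column_names(g)[[1]], "seqname")
  w <- read_track(write_fixture(c("fixedStep chrom=chr1 start=1", "5")))
  expect_identical(column_names(w), c("chrom", "start", "end", "value"))
  expect_error(read_track(write_fixture("not a track at all")),
               class = "genotab_format_error")
})

test_that("open_many honours per-file dialects and fails fast on bad paths", {
  a <- write_fixture(c("a\tb", "1\tx"))
  b <- write_fixture(c("a,c", "2,y"), ext = ".csv")
  tabs <- open_many(c(a, b), list(dialect(header = "first_row"),
                                  dialect(delimiter = ",", header = "first_row")))
  expect_length(tabs, 2L)
  expect_identical(column_names(tabs[[2]]), c("a", "c"))
  expect_identical(unique(provenance(tabs[[1]])), basename(a))

  expect_error(open_many(character(0)), regexp = "no input files")
  expect_error(open_many(c(a, "missing.tsv")), regexp = "missing.tsv",
               class = "genotab_io_error")
})
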