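bed_one <- function(lines) read_track(write_fixture(lines, ".bed"), "bed")

test_that("location merge converts conventions before matching", {
  left <- bed_one("chr1\t100\t200")
  right <- read_track(write_fixture("chr1\tsrc\tf\t151\t250\t.\t+\t.\tg"), "gff")
  m <- merge_by_location(left, right, join_spec("inner", "overlap"))
  expect_equal(n_rows(m), 1L)
  expect_identical(provenance(m), paste0(unique(provenance(left)), "+",
                                         unique(provenance(right))))

  exact0 <- merge_by_location(left, right, join_spec("inner", "exact_interval"))
  expect_equal(n_rows(exact0), 0L)
  exact_lo <- merge_by_location(left, right,
                                join_spec("left_outer", "exact_interval"))
  expect_equal(n_rows(exact_lo), 1L)
  expect_true(is.na(column_values(exact_lo, "attribute")[[1]]))

  # exact match after conversion: BED 100-200 vs GFF 101-200
  right2 <- read_track(write_fixture("chr1\tsrc\tf\t101\t200\t.\t+\t.\tg"), "gff")
  expect_equal(n_rows(merge_by_location(left, right2,
                                        join_spec("inner", "exact_interval"))), 1L)
})

test_that("multiplicity controls pair expansion and first-match tie break", {
  left <- bed_one("chr1\t100\t200")
  right <- bed_one(c("chr1\t150\t160\ta", "chr1\t120\t130\tb", "chr1\t190\t300\tc"))
  mall <- merge_by_location(left, right, join_spec("inner", "overlap"))
  expect_equal(n_rows(mall), 3L)
  mfirst <- merge_by_location(left, right,
                              join_spec("inner", "overlap",
                                        multiplicity = "first_match"))
  expect_equal(n_rows(mfirst), 1L)
  expect_identical(column_values(mfirst, "name")[[1]], "a")  # lowest right index
})

test_that("inner location join equals the nested-loop oracle on random tables", {
  set.seed(101)
  left <- random_interval_table(120, label = "L")
  right <- random_interval_table(150, label = "R")
  m <- merge_by_location(left, right, join_spec("inner", "overlap"))
  oracle <- brute_force_pairs(extract_intervals(left), extract_intervals(right))
  expect_equal(n_rows(m), nrow(oracle))
  got <- paste(column_values(m, "id"), column_values(m, "id_2"), sep = "/")
  want <- paste0("r", oracle$left, "/r", oracle$right)
  expect_identical(sort(got), sort(want))
})

test_that("min_fraction is measured against the left interval", {
  set.seed(103)
  left <- random_interval_table(80, label = "L")
  right <- random_interval_table(80, label = "R")
  for (f in c(0.25, 0.75)) {
    m <- merge_by_location(left, right, join_spec("inner", "overlap",
                                                  min_fraction = f))
    oracle <- brute_force_pairs(extract_intervals(left),
                                extract_intervals(right), f)
    expect_equal(n_rows(m), nrow(oracle), info = paste("fraction", f))
  }
})

test_that("left_outer cardinality bounds hold", {
  set.seed(107)
  left <- random_interval_table(60, label = "L")
  right <- random_interval_table(60, label = "R")
  inner <- merge_by_location(left, right, join_spec("inner", "overlap"))
  louter <- merge_by_location(left, right, join_spec("left_outer", "overlap"))
  expect_lte(n_rows(inner), n_rows(louter))
  lo_first <- merge_by_location(left, right,
                                join_spec("left_outer", "overlap",
                                          multiplicity = "first_match"))
  expect_equal(n_rows(lo_first), n_rows(left))
})

test_that("key joins match trimmed text on 1-4 columns, never on missing", {
  A <- make_table(c("CHROM", "POS", "q"),
                  list(c("chr1", "5", "50"), c("chr1", "7 ", "60"),
                       c("chr2", NA, "70")), "L")
  B <- make_table(c("chrom", "position", "gene"),
                  list(c("chr1", "5", "G1"), c("chr1", "7", "G2"),
                       c("chr2", NA, "G3")), "R")
  spec <- join_spec(mode = "inner", predicate = "key_equality",
                    key_columns = c(CHROM = "chrom", POS = "position"))
  m <- merge_by_keys(A, B, spec)
  expect_equal(n_rows(m), 2L)      # trimmed "7 " matches; NA=NA does not
  expect_identical(column_values(m, "gene"), c("G1", "G2"))
  # text comparison: "1" does not match "1.0"
  X <- make_table("k", list("1"), "x")
  Y <- make_table("k", list("1.0"), "y")
  expect_equal(n_rows(merge_by_keys(X, Y, join_spec(
    predicate = "key_equality", key_columns = "k"))), 0L)
})

test_that("key-join feature limit: 1-4 keys succeed, 5 is rejected", {
  cols <- paste0("k", 1:5)
  rows <- list(as.character(1:5), as.character(6:10))
  L <- make_table(cols, rows, "L")
  R <- make_table(cols, rows, "R")
  for (n in 1:4) {
    spec <- join_spec(predicate = "key_equality",
                      key_columns = stats::setNames(cols[1:n], cols[1:n]))
    expect_equal(n_rows(merge_by_keys(L, R, spec)), 2L)
  }
  expect_error(join_spec(predicate = "key_equality",
                         key_columns = stats::setNames(cols, cols)),
               regexp = "max 4", class = "genotab_spec_error")
  expect_error(join_spec(predicate = "key_equality", key_columns = character(0)),
               class = "genotab_spec_error")
  expect_error(merge_by_keys(L, R, join_spec(predicate = "key_equality",
                                             key_columns = c(nope = "k1"))),
               regexp = "nope", class = "genotab_schema_error")
})

test_that("append unions columns in first-appearance order with missing fill", {
  T1 <- make_table(c("a", "b"), list(c("1", "x"), c("2", "y")), "T1")
  T2 <- make_table(c("b", "c"), list(c("p", "q"), c("r", "s"), c("t", "u")), "T2")
  ap <- append_tables(list(T1, T2))
  expect_identical(column_names(ap), c("a", "b", "c"))
  expect_equal(n_rows(ap), 5L)
  expect_identical(column_values(ap, "b"), c("x", "y", "p", "r", "t"))
  expect_true(all(is.na(column_values(ap, "a")[3:5])))
  expect_identical(provenance(ap), c("T1", "T1", "T2", "T2", "T2"))

  single <- append_tables(list(T1))
  expect_identical(single$data, T1$data)
})

test_that("append is associative up to cell identity", {
  A <- make_table(c("a"), list("1"), "A")
  B <- make_table(c("b"), list("2"), "B")
  C <- make_table(c("a", "c"), list(c("3", "4")), "C")
  left_assoc <- append_tables(list(A, append_tables(list(B, C))))
  flat <- append_tables(list(A, B, C))
  expect_identical(left_assoc$data, flat$data)
  expect_identical(provenance(left_assoc), provenance(flat))
})

test_that("every input column survives a merge, suffixed on collision", {
  L <- bed_one("chr1\t1\t10\tx")
  R <- bed_one("chr1\t5\t15\ty")
  m <- merge_by_location(L, R, join_spec("inner", "overlap"))
  expect_true(all(c("chrom", "chrom_2", "name", "name_2") %in% column_names(m)))
  expect_equal(length(column_names(m)), 8L)  # 4 columns per side, all kept
  expect_identical(anyDuplicated(column_names(m)), 0L)
})

test_that("schema errors are raised when a side lacks coordinates", {
  plain <- make_table("a", list("1"), "p")
  located <- bed_one("chr1\t1\t10")
  expect_error(merge_by_location(plain, located, join_spec()),
               class = "genotab_schema_error")
  expect_error(merge_by_location(located, plain, join_spec()),
               class = "genotab_schema_error")
})
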