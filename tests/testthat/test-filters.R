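test_that("predicate filtering: numeric thresholds, missing handling, combine", {
  t <- make_table(c("cons", "gene"),
                  list(c("0.9", "BRCA1"), c("0.5", "TP53"), c(NA, "EGFR"),
                       c("0.95", "LZTR1")), "t")
  kept <- filter_rows(t, predicate("cons", "gt", 0.85))
  expect_identical(column_values(kept, "gene"), c("BRCA1", "LZTR1"))
  kept_keep <- filter_rows(t, predicate("cons", "gt", 0.85, on_missing = "keep"))
  expect_equal(n_rows(kept_keep), 3L)

  expect_identical(filter_rows(t, list())$data, t$data)  # vacuous truth

  p1 <- predicate("cons", "gt", 0.85, on_missing = "keep")
  p2 <- predicate("gene", "contains", "R")
  n_all <- n_rows(filter_rows(t, list(p1, p2), "all"))
  n_any <- n_rows(filter_rows(t, list(p1, p2), "any"))
  expect_gte(n_any, n_all)

  expect_error(filter_rows(t, predicate("gene", "lt", 1)),
               regexp = "gene", class = "genotab_type_error")
  expect_error(filter_rows(t, predicate("nope", "eq", "x")),
               class = "genotab_schema_error")
})

test_that("eq/ne/contains/in_list compare text with trimming", {
  t <- make_table("f", list(" PASS", "fail", NA), "t")
  expect_equal(n_rows(filter_rows(t, predicate("f", "eq", "PASS"))), 1L)
  expect_equal(n_rows(filter_rows(t, predicate("f", "ne", "PASS"))), 1L)
  expect_equal(n_rows(filter_rows(t, predicate("f", "ne", "PASS",
                                               on_missing = "keep"))), 2L)
  expect_equal(n_rows(filter_rows(t, predicate("f", "contains", "ail"))), 1L)
  expect_equal(n_rows(filter_rows(t, predicate("f", "in_list",
                                               c("PASS", "other")))), 1L)
})

test_that("value-list filtering implements the gene-shortlist pattern", {
  t <- make_table("gene", list("BRCA1", "TP53", "EGFR"), "t")
  lst <- write_fixture(c("# shortlist", "", "TP53", " LZTR1"))
  kept <- filter_by_list(t, "gene", lst)
  expect_identical(column_values(kept, "gene"), "TP53")
  inv <- filter_by_list(t, "gene", lst, negate = TRUE)
  expect_identical(column_values(inv, "gene"), c("BRCA1", "EGFR"))
  expect_error(filter_by_list(t, "gene", write_fixture(c("#only", "", "# comments"))),
               class = "genotab_spec_error")
})

make_points <- function(chrom, pos, label = "pts") {
  t <- make_table(c("chrom", "pos"),
                  Map(function(c, p) c(c, as.character(p)), chrom, pos), label)
  set_location_schema(t, location_schema("chrom_pos", c("chrom", "pos"),
                                         "one_closed"))
}

test_that("criteria filtering keeps/drops by overlap, with score pre-filter", {
  vars <- make_points(rep("chr1", 4), c(105, 155, 250, 460))
  crit <- read_track(write_fixture(c(
    "chr1\t100\t120\tc1\t0.9\t+",
    "chr1\t150\t160\tc2\t0.3\t+",
    "chr1\t450\t500\tc3\t0.95\t+")), "bed")
  keep_all <- filter_by_criteria(vars, criteria_spec(crit, "keep_overlapping"))
  expect_identical(column_values(keep_all, "pos"), c("105", "155", "460"))
  drop_all <- filter_by_criteria(vars, criteria_spec(crit, "drop_overlapping"))
  expect_identical(column_values(drop_all, "pos"), "250")

  conserved_only <- filter_by_criteria(vars, criteria_spec(
    crit, "keep_overlapping",
    criteria_predicate = predicate("score", "gt", 0.85)))
  expect_identical(column_values(conserved_only, "pos"), c("105", "460"))
})

test_that("empty criteria behave as declared boundaries", {
  vars <- make_points("chr1", 105)
  empty <- read_track(write_fixture(character(0)), "bed")
  expect_equal(n_rows(filter_by_criteria(vars, criteria_spec(
    empty, "keep_overlapping"))), 0L)
  unchanged <- filter_by_criteria(vars, criteria_spec(empty, "drop_overlapping"))
  expect_identical(unchanged$data, vars$data)
})

test_that("keep and drop polarities partition the input rows", {
  set.seed(19)
  for (rep in 1:5) {
    vars <- random_interval_table(60)
    crit <- random_interval_table(25)
    f <- sample(c(0, 0.5), 1)
    keep <- filter_by_criteria(vars, criteria_spec(crit, "keep_overlapping",
                                                   min_fraction = f))
    drop <- filter_by_criteria(vars, criteria_spec(crit, "drop_overlapping",
                                                   min_fraction = f))
    expect_equal(n_rows(keep) + n_rows(drop), n_rows(vars))
    expect_length(intersect(column_values(keep, "id"),
                            column_values(drop, "id")), 0L)
  }
})

test_that("raising min_fraction never increases the kept row count", {
  set.seed(23)
  vars <- random_interval_table(80)
  crit <- random_interval_table(30)
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    n_rows(filter_by_criteria(vars, criteria_spec(crit, "keep_overlapping",
                                                  min_fraction = f)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("sample-presence filter matches the worked hand count", {
  t <- make_table(c("locus", "sample"),
                  list(c("chr1:100", "S1"), c("chr1:100", "S2"),
                       c("chr2:5", "S1")), "t")
  # observed samples {S1, S2}: chr1:100 presence 1.0, chr2:5 presence 0.5
  kept <- filter_by_sample_presence(t, sample_spec("sample", threshold = 0.75))
  expect_identical(column_values(kept, "locus"), c("chr1:100", "chr1:100"))
  all1 <- filter_by_sample_presence(t, sample_spec("sample", threshold = 1))
  expect_identical(unique(column_values(all1, "locus")), "chr1:100")
  at_most <- filter_by_sample_presence(t, sample_spec("sample", threshold = 0.5,
                                                      direction = "at_most"))
  expect_identical(column_values(at_most, "locus"), "chr2:5")
  # single observed sample: everything passes 0.5
  one <- make_table(c("locus", "sample"), list(c("a", "S1"), c("b", "S1")), "o")
  expect_equal(n_rows(filter_by_sample_presence(
    one, sample_spec("sample", threshold = 0.5))), 2L)
})

test_that("sample-presence filter agrees with the double-loop oracle", {
  set.seed(29)
  for (rep in 1:4) {
    n <- 400
    t <- make_table(c("chrom", "pos", "sample", "geno"),
                    lapply(seq_len(n), function(i) {
                      c(sample(c("chr1", "chr2"), 1),
                        as.character(sample.int(40, 1)),
                        paste0("S", sample.int(6, 1)),
                        sample(c("0/1", "1/1"), 1))
                    }), "t")
    for (thr in c(0.25, 0.5, 0.75, 1)) {
      spec <- sample_spec("sample", identity_columns = c("chrom", "pos"),
                          threshold = thr)
      got <- filter_by_sample_presence(t, spec)
      want <- sample_presence_oracle(t, "sample", c("chrom", "pos"), thr)
      expect_equal(n_rows(got), length(want))
      expect_identical(column_values(got, "pos"),
                       column_values(t, "pos")[want])
    }
  }
})

test_that("sample roster override and degenerate inputs", {
  t <- make_table(c("locus", "sample"),
                  list(c("a", "S1"), c("a", "S2"), c("b", "S1")), "t")
  # declared roster of 4 samples: presence(a) = 0.5
  kept <- filter_by_sample_presence(t, sample_spec("sample", threshold = 0.5,
                                                   total_samples = 4))
  expect_identical(unique(column_values(kept, "locus")), "a")
  allmiss <- make_table(c("locus", "sample"), list(c("a", NA)), "t")
  expect_error(filter_by_sample_presence(allmiss, sample_spec("sample")),
               class = "genotab_data_error")
  expect_error(sample_spec(paste0("s", 1:5)), class = "genotab_spec_error")
  expect_error(sample_spec("s", identity_columns = "s"),
               class = "genotab_spec_error")
  expect_error(sample_spec("s", threshold = 0), class = "genotab_spec_error")
})

test_that("filters return subsequences of the input rows", {
  set.seed(31)
  t <- random_interval_table(50)
  kept <- filter_rows(t, predicate("start", "ge", 2000))
  idx <- match(column_values(kept, "id"), column_values(t, "id"))
  expect_false(is.unsorted(idx))
  expect_identical(column_names(kept), column_names(t))
})
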