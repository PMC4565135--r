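test_that("reading expression + metadata TSVs builds tumour/normal pairs", {
  mat <- tempfile(fileext = ".tsv")
  meta <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA_T\tsA_N\tsB_T\tsB_N",
               "g1\t5.0\t4.0\t5.5\t4.5",
               "g2\t7.0\t7.1\t6.9\t7.0",
               "g3\t2.0\t3.0\t2.5\t3.5"), mat)
  writeLines(c("sample_id\tsubject_id\tphenotype\tstage",
               "sA_T\tA\ttumour\tII",
               "sA_N\tA\tnormal\tII",
               "sB_T\tB\ttumor\t3",
               "sB_N\tB\tnormal\t3"), meta)
  ds <- read_expression(mat, meta, name = "toy")
  expect_s3_class(ds, "paired_dataset")
  expect_equal(ds$n_pairs, 2)
  expect_equal(sort(ds$pairs$subject), c("A", "B"))
  expect_equal(ds$pairs$stage[ds$pairs$subject == "B"], "III")
  expect_equal(unname(ds$values["g1", "sA_T"]), 5.0)

  # a subject with only a tumour sample is dropped with a warning
  writeLines(c("sample_id\tsubject_id\tphenotype\tstage",
               "sA_T\tA\ttumour\tII",
               "sA_N\tA\tnormal\tII",
               "sB_T\tB\ttumour\tIII"), meta)
  expect_warning(ds2 <- read_expression(mat, meta), "unpartnered")
  expect_equal(ds2$n_pairs, 1)

  # round trip preserves values and pairing
  m2 <- tempfile(fileext = ".tsv")
  md2 <- tempfile(fileext = ".tsv")
  write_expression(ds, m2, md2)
  ds3 <- read_expression(m2, md2, name = "toy")
  expect_equal(ds3$values[rownames(ds$values), colnames(ds$values)], ds$values)
  expect_equal(ds3$pairs[order(ds3$pairs$subject), ],
               ds$pairs[order(ds$pairs$subject), ],
               ignore_attr = TRUE)
})

test_that("malformed inputs are rejected with informative errors", {
  mat <- tempfile(fileext = ".tsv")
  meta <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsubject_id\tphenotype\tstage",
               "sA_T\tA\ttumour\tII",
               "sA_N\tA\tnormal\tII"), meta)
  writeLines(c("gene_id\tsA_T\tsA_N", "g1\t1.0\t2.0", "g1\t3.0\t4.0"), mat)
  expect_error(read_expression(mat, meta), "duplicate gene id")
  writeLines(c("gene_id\tsA_T\tsA_N", "g1\t1.0\t2.0", "g2\toops\t4.0"), mat)
  expect_error(read_expression(mat, meta), "non-numeric.*line 2")
  writeLines(c("gene_id\tsA_T\tsA_N", "g1\t1.0\t2.0"), mat)
  writeLines(c("sample_id\tsubject_id\tphenotype\tstage",
               "sA_T\tA\ttumour\tII",
               "sB_N\tB\tnormal\tII"), meta)
  expect_error(expect_warning(read_expression(mat, meta)), "zero.*pairs")
})

test_that("linear-scale input is log2-transformed on read", {
  mat <- tempfile(fileext = ".tsv")
  meta <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsA_T\tsA_N", "g1\t15\t3"), mat)
  writeLines(c("sample_id\tsubject_id\tphenotype\tstage",
               "sA_T\tA\ttumour\tII", "sA_N\tA\tnormal\tII"), meta)
  ds <- read_expression(mat, meta, log2_input = FALSE)
  expect_equal(unname(ds$values["g1", ]), c(log2(16), log2(4)),
               ignore_attr = TRUE)
})

test_that("universe intersection is a sorted, order-insensitive intersection", {
  d1 <- make_dataset(matrix(rnorm(6), 3, 2,
                            dimnames = list(c("a", "b", "c"), NULL)))
  d2 <- make_dataset(matrix(rnorm(6), 3, 2,
                            dimnames = list(c("b", "c", "d"), NULL)))
  expect_equal(intersect_universes(list(d1, d2)), c("b", "c"))
  expect_equal(intersect_universes(list(d2, d1)), c("b", "c"))
  expect_equal(intersect_universes(list(d1)), sort(gene_universe(d1)))
  # idempotent: intersecting again with the result changes nothing
  expect_equal(intersect_universes(list(d1, d2, c("b", "c"))), c("b", "c"))
  d3 <- make_dataset(matrix(rnorm(4), 2, 2,
                            dimnames = list(c("x", "y"), NULL)))
  expect_error(intersect_universes(list(d1, d3)), "empty intersection")
})

test_that("stage filtering keeps the pair counts of grouped stages", {
  # 19 pairs: 8 stage II, 7 stage III, 4 stage IV
  vals <- matrix(rnorm(5 * 38), 5, 38,
                 dimnames = list(sprintf("g%d", 1:5), NULL))
  stages <- c(rep("II", 8), rep("III", 7), rep("IV", 4))
  ds <- make_dataset(vals, name = "study", stages = stages)
  expect_equal(filter_by_stage(ds, c("II", "III"))$n_pairs, 15)
  expect_equal(filter_by_stage(ds, "IV")$n_pairs, 4)
  expect_equal(filter_by_stage(ds, c("I", "II", "III", "IV"))$n_pairs, 19)
  expect_error(filter_by_stage(ds, "I"), "no pairs remain")
  expect_match(filter_by_stage(ds, c("II", "III"))$name, "S2-3$")
  # disjoint stage groups partition the pairs
  n23 <- filter_by_stage(ds, c("II", "III"))$n_pairs
  n4 <- filter_by_stage(ds, "IV")$n_pairs
  expect_equal(n23 + n4, ds$n_pairs)
})
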