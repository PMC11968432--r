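test_that("omics TSV loads, validates and round-trips bit-exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  body <- write_tiny_omics(f)
  b <- read_omics_block(f, "expression")
  expect_s3_class(b, "omics_block")
  expect_equal(dim(b$values), c(3, 4))
  expect_identical(b$sample_ids, c("s1", "s2", "s3", "s4"))
  expect_equal(unname(b$values), body)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_omics_block(b, out)
  b2 <- read_omics_block(out, "expression")
  expect_identical(b2$values, b$values)
})

test_that("probe rows above the missing-rate threshold are dropped, the rest imputed", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2\ts3\ts4",
               "pA\t1\t2\t3\t4",
               "pB\tNA\tNA\t5\t6",     # 50% missing > 10% -> dropped
               "pC\t1\t1\t1\t1"), f)
  expect_message(b <- read_omics_block(f, "expression"), "dropped")
  expect_equal(nrow(b$values), 2)
  expect_false("pB" %in% b$probe_ids)

  # a single missing entry in a wide row is imputed with the probe median
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("probe_id", paste0("s", 1:12)), collapse = "\t"),
               paste(c("pA", 1:12), collapse = "\t"),
               paste(c("pB", "NA", 2:12), collapse = "\t")), f2)
  b2 <- read_omics_block(f2, "expression")
  expect_equal(unname(b2$values["pB", 1]), median(2:12))
})

test_that("duplicate identifiers and non-numeric bodies are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2\ts1\ts4", "pA\t1\t2\t3\t4", "pB\t1\t2\t3\t4"), f)
  expect_error(read_omics_block(f, "expression"), "duplicate sample")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2\ts3", "pA\t1\tx\t3", "pB\t1\t2\t3"), f2)
  expect_error(read_omics_block(f2, "expression"), "non-numeric")
})

test_that("column permutation permutes sample ids and leaves probe statistics alone", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  body <- write_tiny_omics(f1)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  perm <- c(3, 1, 4, 2)
  write_tiny_omics(f2, body[, perm], samples = c("s1", "s2", "s3", "s4")[perm])
  b1 <- read_omics_block(f1, "expression")
  b2 <- read_omics_block(f2, "expression")
  expect_identical(b2$values[, b1$sample_ids], b1$values)
  expect_equal(rowMeans(b1$values), rowMeans(b2$values))
})

test_that("edge sets deduplicate, drop self-loops, and resolve against probes", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tB", "B\tA", "C\tC"), f)
  expect_message(e <- read_edge_set(f), "self-loop")
  expect_equal(length(e), 1L)
  expect_identical(sort(c(e$from, e$to)), c("A", "B"))

  tri <- edge_set(c("A", "B", "A"), c("B", "C", "C"))
  expect_equal(length(tri), 3L)

  expect_warning(idx <- align_edges(tri, c("A", "B", "Z")), "dropped")
  expect_equal(nrow(idx), 1L)

  f2 <- withr::local_tempfile(fileext = ".sif")
  writeLines(character(0), f2)
  expect_error(read_edge_set(f2), "empty")
})

test_that("config defaults load, unknown keys and bad ranges are rejected", {
  cfg <- load_config(NULL)
  expect_identical(cfg, validate_config(default_config()))

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("seed: 17", f)
  expect_equal(load_config(f)$seed, 17L)

  writeLines("no_such_key: 1", f)
  expect_error(load_config(f), "unknown configuration key")

  writeLines(c("fusion_a: 2", "fusion_b: 1"), f)
  expect_error(load_config(f), "a must be < b")

  writeLines("omega: -0.5", f)
  expect_error(load_config(f), "omega")
})
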