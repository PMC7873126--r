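test_that("a triplet round-trips through write and read unchanged", {
  m <- matrix(c(1.5, 0, NA, 2.25, 1e6, 3,
                4, NA, 0.001, 7, 8, 9), nrow = 3,
              dimnames = list(c("f1", "f2", "f3"), c("a", "b", "c", "d")))
  ft <- tiny_table(m, roles = c("study", "qc_pool", "blank", "study"),
                   species = c("AAA", NA, NA, "BBB"))
  dir <- withr::local_tempdir()
  paths <- write_w4m(ft, dir)
  back <- read_w4m(paths["dataMatrix"], paths["sampleMetadata"],
                   paths["variableMetadata"])
  expect_identical(rownames(back$matrix), rownames(ft$matrix))
  expect_identical(colnames(back$matrix), colnames(ft$matrix))
  expect_equal(back$matrix, ft$matrix, tolerance = 1e-9)
  expect_identical(back$sample_meta$role, ft$sample_meta$role)
  expect_identical(table(back$sample_meta$role), table(ft$sample_meta$role))
})

test_that("random tables round-trip within 1e-9 relative tolerance", {
  set.seed(42)
  m <- matrix(rlnorm(100, 5, 2), 10, 10)
  ft <- tiny_table(m)
  dir <- withr::local_tempdir()
  p <- write_w4m(ft, dir)
  back <- read_w4m(p[1], p[2], p[3])
  expect_equal(back$matrix, ft$matrix, tolerance = 1e-9)
})

test_that("an empty table writes header-only files", {
  ft <- feature_table(matrix(numeric(0), 0, 0),
                      data.frame(sample_id = character(0), role = character(0)),
                      data.frame(feature_id = character(0), mz = numeric(0),
                                 rt = numeric(0)), "NA")
  dir <- withr::local_tempdir()
  p <- write_w4m(ft, dir)
  for (f in p) expect_length(readLines(f), 1L)
})

test_that("NA cells are serialized as the literal token NA", {
  m <- matrix(c(1, NA, 3, 4), 2, 2)
  ft <- tiny_table(m)
  dir <- withr::local_tempdir()
  p <- write_w4m(ft, dir)
  lines <- readLines(p["dataMatrix"])
  expect_true(any(grepl("\tNA", lines, fixed = TRUE)))
})

test_that("identifier mismatches raise instead of intersecting", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  ft <- tiny_table(m)
  dir <- withr::local_tempdir()
  p <- write_w4m(ft, dir)
  # a matrix column absent from sampleMetadata
  dm <- readLines(p["dataMatrix"])
  dm[1] <- sub("s2", "S9", dm[1])
  writeLines(dm, p["dataMatrix"])
  expect_error(read_w4m(p[1], p[2], p[3]), "unmatched sample")
})

test_that("duplicate identifiers and negative intensities are rejected", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("f1", "f1"), c("s1", "s2")))
  expect_error(tiny_table(m), "duplicate")
  m2 <- matrix(c(-1, 2, 3, 4), 2, 2)
  expect_error(tiny_table(m2), "negative")
})

test_that("a transposed dataMatrix is rejected, not guessed", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  ft <- tiny_table(m)
  dir <- withr::local_tempdir()
  p <- write_w4m(ft, dir)
  dm <- read.table(p["dataMatrix"], sep = "\t", header = TRUE,
                   check.names = FALSE)
  tr <- cbind(sample_id = c("s1", "s2"),
              setNames(as.data.frame(t(dm[, -1])), dm[[1]]))
  write.table(tr, p["dataMatrix"], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_w4m(p[1], p[2], p[3]), "transposed")
})

test_that("a generated 500 x 60 triplet reads back with full metadata counts", {
  set.seed(7)
  m <- matrix(rlnorm(500 * 60, 5, 1), 500, 60)
  m[runif(length(m)) < 0.5] <- NA
  ft <- tiny_table(m)
  dir <- withr::local_tempdir()
  p <- write_w4m(ft, dir)
  back <- read_w4m(p[1], p[2], p[3])
  expect_equal(nrow(back$feature_meta), 500L)
  expect_equal(nrow(back$sample_meta), 60L)
  expect_equal(dim(back), c(500L, 60L))
})

test_that("common metadata aliases map onto the canonical schema", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  writeLines(c("feature_id\ts1\ts2", "f1\t1\t3", "f2\t2\t4"),
             file.path(dir, "dm.tsv"))
  writeLines(c("sample_id\tsampleType\tbatch\tinjectionOrder",
               "s1\tsample\tpos01\t1", "s2\tpool\tpos01\t2"),
             file.path(dir, "sm.tsv"))
  writeLines(c("feature_id\tmz\trt", "f1\t100\t200", "f2\t200\t300"),
             file.path(dir, "vm.tsv"))
  ft <- read_w4m(file.path(dir, "dm.tsv"), file.path(dir, "sm.tsv"),
                 file.path(dir, "vm.tsv"))
  expect_identical(ft$sample_meta$role, c("study", "qc_pool"))
  expect_identical(ft$sample_meta$batch_id, c("pos01", "pos01"))
  expect_identical(ft$sample_meta$injection_index, c(1L, 2L))
})

test_that("Lab-IDs parse into number, year and season", {
  out <- parse_lab_id(c("013_2017_A", "013_2017_C"))
  expect_equal(out$number, c(13L, 13L))
  expect_equal(out$year, c(2017L, 2017L))
  expect_equal(out$season, c("A", "C"))
  expect_error(parse_lab_id("000_2017_E"), "outside")
  expect_error(parse_lab_id("129_2017_A"), "001-128")
  expect_error(parse_lab_id("13_2017_A"), "malformed")
})
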