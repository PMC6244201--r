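test_that("count_table validates ids, signs and integrality", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  ct <- count_table(m)
  expect_s3_class(ct, "count_table")
  expect_identical(dim(ct), c(2L, 3L))

  expect_error(count_table(m, feature_ids = c("f1", "f1")), "duplicated feature")
  expect_error(count_table(m, sample_ids = c("s", "s", "s")), "duplicated sample")
  m2 <- m; m2[1, 1] <- -1
  expect_error(count_table(m2), "non-negative")
  m3 <- matrix(c(1.5, 1, 1, 1), 2, 2)
  expect_error(count_table(m3), "integers")
  expect_error(count_table(m, taxonomy = "only-one"), "taxonomy length")
})

test_that("TSV count tables read back what was written", {
  ct <- count_table(matrix(rpois(12, 20), 3, 4,
                           dimnames = list(paste0("esv", 1:3), paste0("s", 1:4))),
                    taxonomy = c("Bacteria;Firmicutes", "Bacteria;Bacteroidetes",
                                 "Bacteria;Proteobacteria"))
  path <- tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  back <- load_count_table(path, "tsv")
  expect_identical(back$counts, ct$counts)
  expect_identical(back$taxonomy, ct$taxonomy)

  # 3 x 2 with sample-id header
  p2 <- write_tsv_fixture(data.frame(feature_id = c("a", "b", "c"),
                                     s1 = c(1L, 0L, 3L), s2 = c(2L, 5L, 0L)))
  ct2 <- load_count_table(p2, "tsv")
  expect_identical(dim(ct2), c(3L, 2L))
  expect_identical(ct2$counts["b", "s2"], 5L)

  # transpose flag flips orientation
  ct3 <- load_count_table(p2, "tsv", transpose = TRUE)
  expect_identical(dim(ct3), c(2L, 3L))
})

test_that("malformed count files raise parse or validation errors", {
  empty <- tempfile(); file.create(empty)
  expect_error(load_count_table(empty, "tsv"), "parse error")
  expect_error(load_count_table(tempfile(), "tsv"), "does not exist")

  dup <- write_tsv_fixture(data.frame(feature_id = c("a", "a"),
                                      s1 = c(1L, 2L), s2 = c(3L, 4L)))
  expect_error(load_count_table(dup, "tsv"), "duplicated feature")

  neg <- write_tsv_fixture(data.frame(feature_id = c("a", "b"),
                                      s1 = c(1L, -2L), s2 = c(3L, 4L)))
  expect_error(load_count_table(neg, "tsv"), "non-negative")
})

test_that("BIOM-style JSON tables load through biomformat", {
  skip_if_not_installed("biomformat")
  m <- matrix(c(5L, 0L, 2L, 7L, 1L, 3L), 3, 2,
              dimnames = list(paste0("esv", 1:3), c("sA", "sB")))
  path <- tempfile(fileext = ".biom")
  rows <- paste(sprintf('{"id":"%s","metadata":null}', rownames(m)), collapse = ",")
  cols <- paste(sprintf('{"id":"%s","metadata":null}', colnames(m)), collapse = ",")
  dat <- paste(apply(m, 1, function(r) paste0("[", paste(r, collapse = ","), "]")),
               collapse = ",")
  writeLines(sprintf(paste0(
    '{"id":"x","format":"Biological Observation Matrix 1.0.0",',
    '"format_url":"http://biom-format.org","type":"OTU table",',
    '"generated_by":"test","date":"2024-01-01T00:00:00",',
    '"matrix_type":"dense","matrix_element_type":"int","shape":[3,2],',
    '"rows":[%s],"columns":[%s],"data":[%s]}'), rows, cols, dat), path)
  ct <- load_count_table(path, "biom-json")
  expect_identical(unname(ct$counts), unname(m))
  expect_identical(rownames(ct$counts), rownames(m))
})

test_that("filtering applies the depth, count and abundance rules", {
  m <- cbind(s1 = c(9000L, 0L, 0L), s2 = c(10000L, 150L, 9L),
             s3 = c(10500L, 160L, 8L))
  rownames(m) <- c("dominant", "mid", "rare")
  ct <- count_table(m)
  # sample below the 10,100-read water-control depth is removed
  f <- filter_features(ct, min_sample_depth = 10100)
  expect_false("s1" %in% colnames(f$counts))
  expect_true(all(c("s2", "s3") %in% colnames(f$counts)))

  # feature whose maximum count is below 10 is removed
  m2 <- rbind(keep = c(100L, 100L, 100L), weak = c(3L, 7L, 9L))
  f2 <- filter_features(count_table(m2), min_max_count = 10)
  expect_identical(rownames(f2$counts), "keep")

  # all-zero thresholds are the identity
  f3 <- filter_features(ct, 0, 0, 0)
  expect_identical(f3$counts, ct$counts)

  # abundance rule: mean relative abundance below 1%
  m3 <- rbind(big = c(990L, 990L), small = c(10L, 10L))
  f4 <- filter_features(count_table(m3), min_mean_rel_abund = 0.011)
  expect_identical(rownames(f4$counts), "big")
  # prevalence mode keeps features present in enough samples
  m4 <- rbind(everywhere = c(5L, 5L, 5L, 5L), once = c(20L, 0L, 0L, 0L))
  f5 <- filter_features(count_table(m4), min_mean_rel_abund = 0.5,
                        mode = "prevalence")
  expect_identical(rownames(f5$counts), "everywhere")

  expect_error(filter_features(ct, min_sample_depth = 1e9), "empty result")
})

test_that("filtering is idempotent", {
  set.seed(4)
  m <- matrix(rnbinom(60 * 30, mu = 60, size = 0.4), 60, 30)
  ct <- count_table(m)
  once <- filter_features(ct, 500, 10, 0.01)
  twice <- filter_features(once, 500, 10, 0.01)
  expect_identical(once$counts, twice$counts)
})

test_that("metadata readers enforce declared categorical levels", {
  p <- write_tsv_fixture(data.frame(sample_id = c("s1", "s2"),
                                    site = c("siteA", "siteB"),
                                    bmi_class = c("lean", "obese"), age = c(31, 44)))
  meta <- read_sample_metadata(p)
  expect_identical(levels(meta$bmi_class), c("lean", "obese"))

  bad <- write_tsv_fixture(data.frame(sample_id = c("s1", "s2"),
                                      bmi_class = c("lean", "chunky")))
  expect_error(read_sample_metadata(bad), "undeclared level")
  dup <- write_tsv_fixture(data.frame(sample_id = c("s1", "s1")))
  expect_error(read_sample_metadata(dup), "duplicated sample_id")
})
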