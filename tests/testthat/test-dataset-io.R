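test_that("CSV reading builds records and class proportions", {
  path <- write_temp_csv(data.frame(id = c("a", "b", "c"),
                                    smiles = c("CCO", "c1ccccc1", "CCN"),
                                    label = c(1, 0, 1)))
  ds <- read_dataset(path, "csv")
  expect_s3_class(ds, "ditp_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(unname(class_proportions(ds)), c(1 / 3, 2 / 3))
  expect_length(attr(ds, "rejected_rows"), 0)
})

test_that("rows with unparseable SMILES are rejected and reported by row number", {
  path <- write_temp_csv(data.frame(id = c("a", "bad", "c"),
                                    smiles = c("CCO", "C1CC", "CCN"),
                                    label = c(1, 0, 1)))
  expect_warning(ds <- read_dataset(path, "csv"), "row 2")
  expect_equal(nrow(ds), 2)
  expect_equal(attr(ds, "rejected_rows"), 2L)
  expect_error(read_dataset(path, "csv", drop_invalid = FALSE), "row 2")
})

test_that("structural dataset errors are raised: duplicates, bad labels, missing pieces", {
  path <- write_temp_csv(data.frame(id = c("a", "a"), smiles = c("C", "CC"),
                                    label = c(1, 0)))
  expect_error(read_dataset(path, "csv"), "duplicate")
  path2 <- write_temp_csv(data.frame(id = c("a", "b"), smiles = c("C", "CC"),
                                     label = c(2, 0)))
  expect_error(read_dataset(path2, "csv"), "non-binary")
  expect_error(read_dataset(tempfile(), "csv"), "not found")
  path3 <- write_temp_csv(data.frame(name = "a", smiles = "C", label = 1))
  expect_error(read_dataset(path3, "csv"), "missing")
})

test_that("textual labels require an explicit mapping and then coerce", {
  path <- write_temp_csv(data.frame(id = c("a", "b"), smiles = c("CCO", "CC"),
                                    label = c("toxicant", "nontoxicant")))
  expect_error(read_dataset(path, "csv"), "non-binary")
  ds <- read_dataset(path, "csv",
                     column_map = list(label_values = list(toxicant = 1,
                                                           nontoxicant = 0)))
  expect_equal(ds$label, c(1L, 0L))
})

test_that("SMI format reads whitespace-separated records", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol1 1", "c1ccccc1 mol2 0"), path)
  ds <- read_dataset(path, "smi")
  expect_equal(ds$id, c("mol1", "mol2"))
  expect_equal(ds$label, c(1L, 0L))
})

test_that("stratified split reproduces the study's 8:2 arithmetic", {
  ds <- toy_dataset(225, rep(c(1, 0), c(93, 132)))
  sp <- stratified_split(ds, 0.8, seed = 42)
  expect_equal(nrow(sp$train), 180)
  expect_equal(nrow(sp$external), 45)
  # explicit override reproduces published per-class counts exactly
  sp2 <- stratified_split(ds, 0.8, seed = 42,
                          per_class_counts = c(pos = 75, neg = 105))
  expect_equal(sum(sp2$train$label == 1), 75)
  expect_equal(sum(sp2$train$label == 0), 105)
  expect_equal(nrow(sp2$external), 45)
})

test_that("largest-remainder allocation stays within 1 of the exact quota", {
  ds <- toy_dataset(10, rep(c(1, 0), each = 5))
  sp <- stratified_split(ds, 0.8, seed = 7)
  expect_equal(sum(sp$train$label == 1), 4)
  expect_equal(sum(sp$train$label == 0), 4)
  for (n_pos in c(7, 13, 29)) {
    dsx <- toy_dataset(n_pos + 31, rep(c(1, 0), c(n_pos, 31)))
    spx <- stratified_split(dsx, 0.8, seed = 1)
    expect_lt(abs(sum(spx$train$label == 1) - 0.8 * n_pos), 1)
    expect_lt(abs(sum(spx$train$label == 0) - 0.8 * 31), 1)
  }
})

test_that("splits partition the dataset and are seed-reproducible", {
  ds <- toy_dataset(37, rep(c(1, 0), c(17, 20)))
  for (seed in 1:200) {
    sp <- stratified_split(ds, 0.7, seed = seed)
    expect_setequal(c(sp$train$id, sp$external$id), ds$id)
    expect_length(intersect(sp$train$id, sp$external$id), 0)
  }
  a <- stratified_split(ds, 0.7, seed = 123)
  b <- stratified_split(ds, 0.7, seed = 123)
  expect_identical(a$train$id, b$train$id)
  expect_identical(a$external$id, b$external$id)
})

test_that("degenerate splits are refused", {
  ds <- toy_dataset(6, rep(c(1, 0), c(2, 4)))
  expect_error(stratified_split(ds, 0.05, seed = 1), "empty")
  expect_error(stratified_split(ds, 1.2, seed = 1), "train_fraction")
  single <- toy_dataset(5, rep(1, 5))
  expect_error(stratified_split(single, 0.8, seed = 1), "both classes")
})

test_that("dataset summaries count classes and flag degenerate input", {
  ds <- toy_dataset(8, rep(c(1, 0), c(3, 5)))
  s <- dataset_summary(ds, properties = FALSE)
  expect_equal(unname(s$counts), c(3, 5))
  expect_false(s$single_class)
  expect_warning(s1 <- dataset_summary(toy_dataset(4, rep(1, 4)),
                                       properties = FALSE), "single class")
  expect_true(s1$single_class)
  empty <- toy_dataset(2, c(0, 1))[0, ]
  class(empty) <- c("ditp_dataset", "data.frame")
  expect_error(dataset_summary(empty), "empty")
})

test_that("dataset construction validates ids and labels", {
  expect_error(ditp_dataset(c("a", "a"), c("C", "C"), c(0, 1)), "duplicate")
  expect_error(ditp_dataset(c("a", ""), c("C", "C"), c(0, 1)), "non-empty")
  expect_error(ditp_dataset("a", "C", 2), "0.*1|labels")
  expect_error(ditp_dataset("a", "C1CC", 1), "unparseable")
})
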