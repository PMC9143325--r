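test_that("generator specs validate their probabilities and geometry", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(n_molecules = 5), "n_molecules")
  expect_error(synthetic_spec(positive_fraction = 0), "positive_fraction")
  expect_error(synthetic_spec(planted_alerts = data.frame(bit = c(1, 1),
                                                          p_pos = 0.8,
                                                          p_neg = 0.1)))
  expect_error(synthetic_spec(n_fragment_bits = 10,
                              planted_alerts = data.frame(bit = 11, p_pos = 0.9,
                                                          p_neg = 0.1)))
})

test_that("identical seeds reproduce the full dataset bit-for-bit", {
  sp <- synthetic_spec(n_molecules = 80, seed = 1234)
  a <- generate_feature_dataset(sp)
  b <- generate_feature_dataset(sp)
  expect_identical(a$fragments$matrix, b$fragments$matrix)
  expect_identical(a$descriptors$matrix, b$descriptors$matrix)
  expect_identical(a$dataset$label, b$dataset$label)
  d <- generate_feature_dataset(synthetic_spec(n_molecules = 80, seed = 1235))
  expect_false(identical(a$fragments$matrix, d$fragments$matrix))
})

test_that("planted-alert enrichment converges to the theoretical value", {
  sp <- synthetic_spec(n_molecules = 10000,
                       planted_alerts = data.frame(bit = 1, p_pos = 0.9,
                                                   p_neg = 0.1),
                       n_descriptors = 2, seed = 2024)
  d <- generate_feature_dataset(sp)
  y <- d$dataset$label
  bit <- d$fragments$matrix[, 1]
  emp <- fragment_frequency(sum(bit & y == 1), length(y), sum(bit), sum(y))
  expect_equal(emp, d$ground_truth$theoretical_freq_P[1], tolerance = 0.05)
})

test_that("class balance and imbalance defaults match the study conditions", {
  d <- generate_feature_dataset(synthetic_spec(n_molecules = 5000, seed = 31))
  expect_equal(mean(d$dataset$label), 0.41, tolerance = 0.05)
  expect_setequal(unique(d$dataset$label), c(0, 1))
})

test_that("null data (no alerts, no shifts) yields chance-level signal", {
  sp <- synthetic_spec(n_molecules = 400, planted_alerts = data.frame(),
                       descriptor_effect_sizes = 0, n_fragment_bits = 100,
                       n_descriptors = 5, seed = 77)
  d <- generate_feature_dataset(sp)
  y <- d$dataset$label
  # CV AUC on uninformative descriptors stays near 0.5
  res <- run_repeated_cv(d$descriptors, y, classifier_spec("knn", list(k = 5)),
                         folds = 5, repeats = 2, seed = 9)
  expect_lte(abs(res$mean[["AUC"]] - 0.5), 3 * res$sd[["AUC"]])
  # max fragment IG sits below the 99th percentile of a label-permutation null
  ig_obs <- max(apply(d$fragments$matrix, 2, information_gain, labels = y))
  set.seed(123)
  null_max <- replicate(100, {
    yp <- sample(y)
    max(apply(d$fragments$matrix, 2, information_gain, labels = yp))
  })
  expect_lte(ig_obs, quantile(null_max, 0.99))
})

test_that("label noise flips labels after feature generation", {
  sp0 <- synthetic_spec(n_molecules = 300, label_noise = 0, seed = 555)
  sp1 <- synthetic_spec(n_molecules = 300, label_noise = 0.3, seed = 555)
  a <- generate_feature_dataset(sp0)
  b <- generate_feature_dataset(sp1)
  expect_identical(a$fragments$matrix, b$fragments$matrix)
  expect_identical(b$ground_truth$labels_pre_noise, a$dataset$label)
  expect_gt(sum(a$dataset$label != b$dataset$label), 0)
})

test_that("synthetic datasets round-trip through the real CSV reader", {
  d <- generate_feature_dataset(synthetic_spec(n_molecules = 20, seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d$dataset, path)
  ds2 <- read_dataset(path, "csv")
  expect_equal(ds2$id, d$dataset$id)
  expect_equal(ds2$label, d$dataset$label)
})

test_that("the end-to-end synthetic pipeline recovers model and alerts", {
  # the canonical recovery condition: 3 alerts at 0.8/0.1, descriptor shift
  # 1.5 sd, n = 300
  sp <- synthetic_spec(n_molecules = 300, n_fragment_bits = 200,
                       planted_alerts = data.frame(bit = 1:3, p_pos = 0.8,
                                                   p_neg = 0.1),
                       n_descriptors = 10, descriptor_effect_sizes = 1.5,
                       seed = 2718)
  d <- generate_feature_dataset(sp)
  # small representation grid, as the pipeline would rank it
  combos <- list(d$descriptors, d$fragments, list(d$descriptors, d$fragments))
  results <- lapply(combos, function(b)
    run_repeated_cv(b, d$dataset$label, classifier_spec("knn", list(k = 5)),
                    folds = 5, repeats = 2, seed = 42))
  best <- select_top(results, 1)[[1]]
  expect_gte(best$mean[["AUC"]], 0.9)
  rep_ <- mine_alerts(d$fragments, d$dataset$label, top_n = 3)
  expect_setequal(rep_$fragment_id, d$ground_truth$planted_bits)
})
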