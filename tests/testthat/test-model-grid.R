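# The CV harness on seeded synthetic data: small problem sizes keep the
# suite fast while still exercising fold geometry, leakage guards and
# ranking determinism.

syn <- generate_feature_dataset(synthetic_spec(
  n_molecules = 100, n_fragment_bits = 30, n_descriptors = 4,
  descriptor_effect_sizes = 2.5, seed = 314))

test_that("the grid is the product of algorithms, representations and settings", {
  blocks <- list(desc = syn$descriptors, frag = syn$fragments)
  grids1 <- lapply(default_grids(), function(g) g[1])   # one setting each
  g <- build_grid(blocks, grids = grids1, seed = 1)
  # 7 algorithms x (2 single blocks + 1 descriptor-fingerprint pair)
  expect_length(g, 7 * 3)
  restricted <- build_grid(blocks["desc"], algorithms = "knn",
                           include_pairs = FALSE)
  expect_length(restricted, length(default_grids()$knn))
  expect_error(build_grid(blocks, algorithms = character(0)), "empty")
  expect_error(build_grid(blocks, algorithms = "deep_net"), "unknown")
  expect_error(build_grid(list(syn$descriptors)), "named")
})

test_that("stratified folds partition each class to within one member", {
  y <- rep(c(1, 0), c(41, 59))
  set.seed(5)
  f <- ditpqsar:::stratified_folds(y, 5)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    expect_lte(abs(sum(f == k & y == 1) - 41 / 5), 1)
    expect_lte(abs(sum(f == k) - 20), 1)
  }
  expect_error(ditpqsar:::stratified_folds(rep(c(1, 0), c(3, 50)), 5), "fewer")
})

test_that("well-separated synthetic classes give a near-perfect k-NN CV AUC", {
  res <- run_repeated_cv(syn$descriptors, syn$dataset$label,
                         classifier_spec("knn", list(k = 5)),
                         folds = 5, repeats = 2, seed = 7)
  expect_s3_class(res, "cv_result")
  expect_equal(nrow(res$fold_metrics), 10)
  expect_gte(res$mean[["AUC"]], 0.95)
})

test_that("permuted labels collapse CV AUC to chance", {
  set.seed(99)
  y_perm <- sample(syn$dataset$label)
  res <- run_repeated_cv(syn$descriptors, y_perm,
                         classifier_spec("knn", list(k = 5)),
                         folds = 5, repeats = 2, seed = 8)
  expect_lte(abs(res$mean[["AUC"]] - 0.5), 3 * res$sd[["AUC"]])
})

test_that("identical seeds give identical CV results, different seeds differ", {
  spec <- classifier_spec("knn", list(k = 3))
  a <- run_repeated_cv(syn$descriptors, syn$dataset$label, spec,
                       folds = 5, repeats = 1, seed = 21)
  b <- run_repeated_cv(syn$descriptors, syn$dataset$label, spec,
                       folds = 5, repeats = 1, seed = 21)
  expect_identical(a$fold_metrics, b$fold_metrics)
  # a different seed reshuffles the folds (checked on noisy labels so the
  # metrics cannot coincide by saturation)
  set.seed(1); y_noisy <- ifelse(runif(100) < 0.25, 1 - syn$dataset$label,
                                 syn$dataset$label)
  d1 <- run_repeated_cv(syn$descriptors, y_noisy, spec,
                        folds = 5, repeats = 1, seed = 21)
  d2 <- run_repeated_cv(syn$descriptors, y_noisy, spec,
                        folds = 5, repeats = 1, seed = 22)
  expect_false(identical(d1$fold_metrics, d2$fold_metrics))
})

test_that("every classifier family trains and scores within [0, 1]", {
  X <- syn$descriptors$matrix
  y <- syn$dataset$label
  for (alg in c("svm_rbf", "knn", "random_forest", "naive_bayes", "ann",
                "adaboost", "xgboost")) {
    params <- switch(alg, ann = list(size = 5, maxit = 50),
                     adaboost = list(n_estimators = 20),
                     xgboost = list(nrounds = 20), list())
    fit <- ditpqsar:::fit_classifier(classifier_spec(alg, params, seed = 3), X, y)
    sc <- ditpqsar:::score_classifier(fit, X)
    expect_length(sc, nrow(X))
    expect_true(all(sc >= 0 & sc <= 1), info = alg)
    expect_gte(auc_score(y, sc), 0.8)           # separable data, training scores
  }
})

test_that("ranking is total, deterministic and tie-broken by MCC then ACC", {
  mk <- function(auc, mcc, acc, alg = "knn") {
    structure(list(algorithm = alg, params = list(k = 5), combo = "b",
                   folds = 5, repeats = 1,
                   mean = c(SE = 0.5, SP = 0.5, ACC = acc, MCC = mcc, AUC = auc),
                   sd = c(SE = 0, SP = 0, ACC = 0, MCC = 0, AUC = 0)),
              class = "cv_result")
  }
  aucs <- c(0.628, 0.621, 0.617, 0.613, 0.612)
  shuffled <- list(mk(0.617, 0.2, 0.6), mk(0.628, 0.3, 0.6), mk(0.612, 0.1, 0.6),
                   mk(0.621, 0.25, 0.6), mk(0.613, 0.15, 0.6))
  top <- select_top(shuffled, 5)
  expect_equal(vapply(top, function(r) r$mean[["AUC"]], 1), aucs)
  tied <- list(mk(0.6, 0.10, 0.7), mk(0.6, 0.30, 0.6), mk(0.6, 0.20, 0.6))
  expect_equal(vapply(select_top(tied, 3), function(r) r$mean[["MCC"]], 1),
               c(0.30, 0.20, 0.10))
  expect_length(select_top(tied, 10), 3)         # n beyond the list: full list
})

test_that("a 1-NN model scores a training member as its own label", {
  spec <- classifier_spec("knn", list(k = 1))
  model <- fit_qsar_model(syn$descriptors, syn$dataset$label, spec, smote = NULL)
  preds <- predict(model, syn$descriptors)
  expect_equal(preds$label, syn$dataset$label)
})

test_that("external scoring is seeded-deterministic and leakage-free", {
  sp <- stratified_split(syn$dataset, 0.8, seed = 5)
  tr <- match(sp$train$id, syn$dataset$id); ex <- match(sp$external$id, syn$dataset$id)
  trb <- ditpqsar:::subset_block(syn$descriptors, tr)
  exb <- ditpqsar:::subset_block(syn$descriptors, ex)
  spec <- classifier_spec("knn", list(k = 5), seed = 2)
  r1 <- fit_and_predict_external(trb, sp$train$label, exb, spec,
                                 external_labels = sp$external$label)
  r2 <- fit_and_predict_external(trb, sp$train$label, exb, spec,
                                 external_labels = sp$external$label)
  expect_identical(r1$predictions, r2$predictions)
  # shuffling the external labels must not change any fitted state or score
  r3 <- fit_and_predict_external(trb, sp$train$label, exb, spec,
                                 external_labels = sample(sp$external$label))
  expect_identical(r1$predictions$score, r3$predictions$score)
  expect_gte(r1$metrics$ACC, 0.8)                # separable external set
  expect_true(all(r1$predictions$score >= 0 & r1$predictions$score <= 1))
})

test_that("consensus averaging is the arithmetic mean with a 0.5 threshold", {
  v <- c(0.2, 0.9, 0.6)
  expect_equal(consensus_predict(replicate(5, v, simplify = FALSE))$score, v)
  one <- consensus_predict(list(c(0.2), c(0.4), c(0.6), c(0.8), c(1.0)))
  expect_equal(one$score, 0.6)
  expect_equal(one$label, 1L)
  expect_error(consensus_predict(list(c(0.1, 0.2), c(0.3))), "misaligned")
  expect_error(consensus_predict(list(c(0.1))), ">= 2")
})
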