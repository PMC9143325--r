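# Model-selection harness: hyperparameter grid construction, 10x-repeated
# stratified 5-fold cross-validation with per-fold preprocessing and SMOTE
# (no leakage into held-out folds), ranking, final refits and consensus.

subset_block <- function(block, idx) {
  feature_block(block$name, block$kind,
                block$matrix[idx, , drop = FALSE], kinds = block$kinds)
}

#' Default hyperparameter grids
#'
#' SVM: C in \{0.1, 1, 10, 100\}; k-NN: k in \{1, 3, 5, 7, 9\}; RF: 50-500
#' trees x \{sqrt, log2\} feature sampling at depth 4; ANN (sgd-style single
#' hidden layer): 50-200 units; AdaBoost: 50-500 estimators; XGBoost: depth
#' 3-6 x min child weight \{1, 3, 5\}; naive Bayes at provider defaults.
#'
#' @return named list of per-algorithm parameter grids (lists of settings).
#' @export
default_grids <- function() {
  expand_named <- function(...) {
    g <- expand.grid(..., stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  list(
    svm_rbf = expand_named(C = c(0.1, 1, 10, 100)),
    knn = expand_named(k = c(1, 3, 5, 7, 9)),
    random_forest = expand_named(ntree = c(50, 100, 200, 500),
                                 max_features = c("sqrt", "log2")),
    naive_bayes = list(list()),
    ann = expand_named(size = c(50, 100, 200)),
    adaboost = expand_named(n_estimators = c(50, 100, 200, 500)),
    xgboost = expand_named(max_depth = 3:6, min_child_weight = c(1, 3, 5)))
}

#' Build the classifier x feature-representation x hyperparameter grid
#'
#' The Cartesian product of the requested algorithms, the feature
#' representations (each single block plus each continuous-descriptor x
#' binary-fingerprint pair) and the per-algorithm hyperparameter settings.
#'
#' @param blocks named list of [feature_block()]s.
#' @param algorithms character vector of algorithm names (default: all 7).
#' @param grids per-algorithm grids (default [default_grids()]).
#' @param include_pairs also form descriptor+fingerprint pair combos
#'   (default `TRUE`).
#' @param seed base seed stored in each spec.
#' @return list of `list(spec = classifier_spec, combo = character vector of
#'   block names)`.
#' @export
build_grid <- function(blocks, algorithms = ALGORITHMS, grids = default_grids(),
                       include_pairs = TRUE, seed = 1) {
  if (!length(algorithms)) stopf("empty algorithm list")
  bad <- setdiff(algorithms, ALGORITHMS)
  if (length(bad)) stopf("unknown algorithm(s): %s", paste(bad, collapse = ", "))
  if (!length(blocks) || is.null(names(blocks))) stopf("blocks must be a named list")
  combos <- as.list(names(blocks))
  if (include_pairs) {
    kinds <- vapply(blocks, function(b) b$kind, "")
    for (d in names(blocks)[kinds == "continuous"])
      for (f in names(blocks)[kinds == "binary"])
        combos[[length(combos) + 1]] <- c(d, f)
  }
  out <- list()
  for (alg in algorithms) {
    settings <- grids[[alg]] %||% list(list())
    for (combo in combos)
      for (p in settings)
        out[[length(out) + 1]] <- list(
          spec = classifier_spec(alg, p, seed = seed), combo = combo)
  }
  out
}

stratified_folds <- function(y, folds) {
  if (min(table(y)) < folds) stopf("a class has fewer members than folds")
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

#' Repeated stratified k-fold cross-validation of one model
#'
#' Within every fold the preprocessor is fit on the fold-training portion
#' only and SMOTE is applied to the fold-training portion only, so held-out
#' estimates are leakage-free. A compatibility switch (`refit_per_fold =
#' FALSE`) instead fits the preprocessor once on the full training set.
#'
#' @param blocks a [feature_block()] or list of blocks (combined by id).
#' @param labels binary vector aligned to block rows.
#' @param spec a [classifier_spec()].
#' @param folds,repeats cross-validation geometry (defaults 5 and 10).
#' @param seed integer; identical seeds give identical results.
#' @param smote SMOTE settings `list(k_neighbors = 5, target_ratio = 1)`, or
#'   `NULL` to disable.
#' @param refit_per_fold refit preprocessing inside every fold (default).
#' @param corr_threshold,extreme_limit passed to [fit_preprocessor()].
#' @return object of class `cv_result` with `fold_metrics`
#'   (`folds * repeats` rows), `mean` and `sd` per metric.
#' @export
run_repeated_cv <- function(blocks, labels, spec, folds = 5, repeats = 10,
                            seed = 1, smote = list(k_neighbors = 5, target_ratio = 1),
                            refit_per_fold = TRUE,
                            corr_threshold = 0.95, extreme_limit = 1e8) {
  block <- if (inherits(blocks, "feature_block")) blocks else combine_blocks(blocks)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(block$matrix))
  pp_full <- if (!refit_per_fold)
    fit_preprocessor(block, corr_threshold, extreme_limit) else NULL
  rows <- with_seed(seed, {
    res <- vector("list", folds * repeats)
    for (r in seq_len(repeats)) {
      fold_id <- stratified_folds(y, folds)
      for (k in seq_len(folds)) {
        tr <- which(fold_id != k); te <- which(fold_id == k)
        pp <- if (refit_per_fold)
          fit_preprocessor(subset_block(block, tr), corr_threshold, extreme_limit)
          else pp_full
        Xtr <- predict(pp, subset_block(block, tr))$matrix
        Xte <- predict(pp, subset_block(block, te))$matrix
        ytr <- y[tr]
        if (!is.null(smote)) {
          bal <- smote_oversample(Xtr, ytr,
                                  k_neighbors = smote$k_neighbors %||% 5,
                                  target_ratio = smote$target_ratio %||% 1,
                                  seed = sample.int(.Machine$integer.max, 1))
          Xtr <- bal$X; ytr <- bal$y
        }
        fold_spec <- spec
        fold_spec$seed <- sample.int(.Machine$integer.max, 1)
        fit <- fit_classifier(fold_spec, Xtr, ytr)
        sc <- score_classifier(fit, Xte)
        ms <- classification_metrics(confusion_from_predictions(y[te], as.integer(sc >= 0.5)))
        ms$AUC <- auc_score(y[te], sc)
        res[[(r - 1) * folds + k]] <- data.frame(
          rep = r, fold = k, SE = ms$SE, SP = ms$SP, ACC = ms$ACC,
          MCC = ms$MCC, AUC = ms$AUC)
      }
    }
    do.call(rbind, res)
  })
  metric_cols <- c("SE", "SP", "ACC", "MCC", "AUC")
  structure(list(
    algorithm = spec$algorithm, params = spec$params,
    combo = block$name, folds = folds, repeats = repeats, seed = seed,
    fold_metrics = rows,
    mean = colMeans(rows[metric_cols]),
    sd = apply(rows[metric_cols], 2, stats::sd)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  ps <- if (length(x$params))
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ",") else ""
  cat(sprintf("<cv_result> %s(%s) on %s: AUC %.3f +/- %.3f, ACC %.1f%%, MCC %.3f (%dx%d-fold)\n",
              x$algorithm, ps, x$combo, x$mean[["AUC"]], x$sd[["AUC"]],
              100 * x$mean[["ACC"]], x$mean[["MCC"]], x$repeats, x$folds))
  invisible(x)
}

model_label <- function(res) {
  ps <- if (length(res$params))
    paste(names(res$params), unlist(res$params), sep = "=", collapse = ",") else "default"
  sprintf("%s-%s(%s)", res$combo, res$algorithm, ps)
}

#' Rank cross-validated models
#'
#' Sorted by mean AUC descending; ties broken by mean MCC, then mean ACC,
#' then lexicographic model label — a total, deterministic order.
#'
#' @param results list of `cv_result`s.
#' @param n number of top models to keep (default 5; the full ranking is
#'   returned when `n` exceeds the list).
#' @return ranked sublist of `results`.
#' @export
select_top <- function(results, n = 5) {
  if (!length(results)) stopf("empty result list")
  auc <- vapply(results, function(r) r$mean[["AUC"]], 1)
  mcc <- vapply(results, function(r) r$mean[["MCC"]], 1)
  acc <- vapply(results, function(r) r$mean[["ACC"]], 1)
  lbl <- vapply(results, model_label, "")
  ord <- order(-auc, -mcc, -acc, lbl)
  results[ord[seq_len(min(n, length(results)))]]
}

#' Cross-validation summary table
#'
#' One row per model with mean +/- sd of each metric, in the layout of the
#' published CV result tables.
#'
#' @param results list of `cv_result`s.
#' @return data.frame.
#' @export
cv_summary_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      model = r$algorithm,
      features = r$combo,
      params = if (length(r$params)) paste(names(r$params), unlist(r$params),
                                           sep = "=", collapse = ",") else "",
      SE = sprintf("%.1f \u00b1 %.1f", 100 * r$mean[["SE"]], 100 * r$sd[["SE"]]),
      SP = sprintf("%.1f \u00b1 %.1f", 100 * r$mean[["SP"]], 100 * r$sd[["SP"]]),
      ACC = sprintf("%.1f \u00b1 %.1f", 100 * r$mean[["ACC"]], 100 * r$sd[["ACC"]]),
      MCC = sprintf("%.3f \u00b1 %.3f", r$mean[["MCC"]], r$sd[["MCC"]]),
      AUC = sprintf("%.3f \u00b1 %.3f", r$mean[["AUC"]], r$sd[["AUC"]]),
      mean_AUC = r$mean[["AUC"]], mean_MCC = r$mean[["MCC"]],
      stringsAsFactors = FALSE)
  }))
}

#' Fit a final QSAR model on the full training set
#'
#' Preprocessing and SMOTE are fit/applied once on the whole training set,
#' then the classifier is fit once; the returned model carries everything
#' needed to score new molecules.
#'
#' @param blocks a [feature_block()] or list of blocks (training rows).
#' @param labels binary training labels.
#' @param spec a [classifier_spec()].
#' @param smote SMOTE settings or `NULL`.
#' @param corr_threshold,extreme_limit passed to [fit_preprocessor()].
#' @return object of class `qsar_model`.
#' @export
fit_qsar_model <- function(blocks, labels, spec,
                           smote = list(k_neighbors = 5, target_ratio = 1),
                           corr_threshold = 0.95, extreme_limit = 1e8) {
  block <- if (inherits(blocks, "feature_block")) blocks else combine_blocks(blocks)
  y <- as.integer(labels)
  pp <- fit_preprocessor(block, corr_threshold, extreme_limit)
  Xtr <- predict(pp, block)$matrix
  if (!is.null(smote)) {
    bal <- smote_oversample(Xtr, y, k_neighbors = smote$k_neighbors %||% 5,
                            target_ratio = smote$target_ratio %||% 1,
                            seed = spec$seed)
    Xtr <- bal$X; y <- bal$y
  }
  fit <- fit_classifier(spec, Xtr, y)
  structure(list(spec = spec, preprocessor = pp, classifier = fit,
                 combo = block$name, train_matrix = Xtr, train_labels = y),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> %s on %s (%d features kept)\n",
              x$spec$algorithm, x$combo, length(x$preprocessor$kept)))
  invisible(x)
}

#' Score new molecules with a fitted QSAR model
#'
#' @param object a `qsar_model`.
#' @param newdata a [feature_block()] or list of blocks covering the model's
#'   features.
#' @param ... unused.
#' @return data.frame with `score` in `[0, 1]` and hard `label`
#'   (score >= 0.5).
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  block <- if (inherits(newdata, "feature_block")) newdata else combine_blocks(newdata)
  Xe <- predict(object$preprocessor, block)$matrix
  sc <- score_classifier(object$classifier, Xe)
  data.frame(id = rownames(Xe), score = sc, label = as.integer(sc >= 0.5),
             stringsAsFactors = FALSE)
}

#' Train on the full training set and score the external set
#'
#' @param train_blocks,external_blocks blocks (or lists of blocks) for the
#'   two partitions; external molecules must be featurized with the same
#'   blocks.
#' @param labels binary training labels.
#' @param spec a [classifier_spec()].
#' @param external_labels optional; when given, external metrics (incl. AUC)
#'   are attached.
#' @param ... passed to [fit_qsar_model()].
#' @return `list(model, predictions, metrics)`.
#' @export
fit_and_predict_external <- function(train_blocks, labels, external_blocks,
                                     spec, external_labels = NULL, ...) {
  model <- fit_qsar_model(train_blocks, labels, spec, ...)
  preds <- predict(model, external_blocks)
  metrics <- NULL
  if (!is.null(external_labels)) {
    metrics <- classification_metrics(
      confusion_from_predictions(external_labels, preds$label))
    metrics$AUC <- auc_score(external_labels, preds$score)
  }
  list(model = model, predictions = preds, metrics = metrics)
}

#' Consensus prediction by score averaging
#'
#' @param score_lists list of >= 2 aligned score vectors (one per model).
#' @return data.frame with the per-molecule arithmetic mean `score` and hard
#'   `label` at 0.5.
#' @export
consensus_predict <- function(score_lists) {
  if (length(score_lists) < 2) stopf("consensus needs >= 2 score vectors")
  len <- unique(vapply(score_lists, length, 1L))
  if (length(len) != 1) stopf("misaligned score vectors (lengths %s)",
                              paste(vapply(score_lists, length, 1L), collapse = ", "))
  sc <- rowMeans(do.call(cbind, score_lists))
  data.frame(score = sc, label = as.integer(sc >= 0.5))
}
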