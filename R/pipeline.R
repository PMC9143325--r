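# Config-driven end-to-end run: dataset -> features -> split -> CV model
# selection -> external validation (+ consensus) -> applicability domain ->
# structural alerts, with every artifact written as CSV/JSON under one run
# directory and the full configuration + seed recorded in a manifest.

#' Read a pipeline run configuration
#'
#' JSON (always available) or YAML (when the yaml package is installed).
#'
#' @param path config file path (`.json`, `.yml`/`.yaml`).
#' @return config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("YAML configs need the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

default_run_config <- function() {
  list(
    seed = 1,
    synthetic = list(n_molecules = 225, positive_fraction = 0.41,
                     n_fragment_bits = 200, n_descriptors = 10,
                     descriptor_effect_sizes = 1.5,
                     background_bit_probability = 0.1),
    split = list(train_fraction = 0.8),
    algorithms = c("knn", "naive_bayes"),
    grids = NULL,                    # NULL -> default_grids() restricted to algorithms
    include_pairs = TRUE,
    cv = list(folds = 5, repeats = 10),
    smote = list(k_neighbors = 5, target_ratio = 1),
    top_n = 5,
    ad = list(percentile = 0.95, method = "nn"),
    alerts = list(min_occurrences = 7, top_n = 10, scope = "full"))
}

config_hash <- function(config) {
  # cheap structural digest: stable serialization -> 31-bit polynomial hash
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

pipeline_blocks <- function(config, ds) {
  blocks <- list()
  if (!is.null(config$synthetic)) {
    syn <- attr(ds, "synthetic_blocks")
    blocks$synthetic_descriptors <- syn$descriptors
    blocks$synthetic_fragments <- syn$fragments
  }
  for (bk in config$blocks %||% list()) {
    blk <- switch(bk$type,
      fingerprint = compute_fingerprint(ds, bk$family, nbits = bk$nbits %||% 1024),
      descriptors = compute_descriptors(ds, bk$set),
      table = load_feature_table(bk$path, bk$kind, bk$name, ds$id),
      smarts = smarts_block(ds, unlist(bk$patterns), bk$name %||% "smarts"),
      stopf("unknown block type '%s'", bk$type))
    blocks[[blk$name]] <- blk
  }
  if (!length(blocks)) stopf("configuration defines no feature blocks")
  blocks
}

#' Run the full pipeline
#'
#' Emits, in order: dataset summary, feature-block manifest, CV results
#' table, external validation table (with consensus row when >= 2 finalists),
#' applicability-domain coverage table, structural-alert report, and a
#' machine-readable run manifest (config + seed + config hash + package
#' version). Reruns with the same config and seed produce identical tables.
#'
#' @param config list (see [read_run_config()] / `default_run_config`): either
#'   a `synthetic` spec or a `data` entry (`path`, `format`, `column_map`),
#'   plus optional `blocks`, `algorithms`, `grids`, `split`, `cv`, `smote`,
#'   `top_n`, `ad`, `alerts`, `seed`.
#' @param output_dir run directory (created; must not be an existing
#'   non-empty run unless `overwrite = TRUE`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the run artifacts (`summary`, `cv`,
#'   `external`, `ad`, `alerts`, `manifest`, `output_dir`).
#' @export
run_pipeline <- function(config = list(), output_dir, overwrite = FALSE) {
  config <- utils::modifyList(default_run_config(), config)
  if (dir.exists(output_dir) && length(dir(output_dir)) && !overwrite)
    stopf("output_dir %s exists and is non-empty", output_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  hash <- config_hash(config)

  # validate fast-failing pieces before any heavy work
  bad_alg <- setdiff(config$algorithms, ALGORITHMS)
  if (length(bad_alg)) stopf("unknown algorithm(s) in config: %s",
                             paste(bad_alg, collapse = ", "))
  for (bk in config$blocks %||% list())
    if (!bk$type %in% c("fingerprint", "descriptors", "table", "smarts"))
      stopf("unknown block type '%s' in config", bk$type)

  # --- stage 1: dataset
  if (!is.null(config$data)) {
    ds <- read_dataset(config$data$path, config$data$format %||% "csv",
                       config$data$column_map %||% list())
  } else {
    sp_args <- config$synthetic
    sp_args$seed <- sp_args$seed %||% seed
    if (!is.null(sp_args$planted_alerts))
      sp_args$planted_alerts <- as.data.frame(sp_args$planted_alerts)
    syn <- generate_feature_dataset(do.call(synthetic_spec, sp_args))
    ds <- syn$dataset
    attr(ds, "synthetic_blocks") <- syn[c("fragments", "descriptors")]
  }
  summ <- dataset_summary(ds, properties = is.null(config$synthetic))
  write_json_artifact(list(n = summ$n, counts = as.list(summ$counts),
                           proportions = as.list(summ$proportions),
                           config_hash = hash, seed = seed),
                      file.path(output_dir, "dataset_summary.json"))

  # --- stage 2: features
  blocks <- pipeline_blocks(config, ds)
  manifest_df <- data.frame(
    block = names(blocks),
    kind = vapply(blocks, function(b) b$kind, ""),
    n_features = vapply(blocks, function(b) ncol(b$matrix), 1L))
  write_csv_artifact(manifest_df, file.path(output_dir, "feature_manifest.csv"), hash)

  # --- stage 3: split
  sp <- stratified_split(ds, config$split$train_fraction %||% 0.8, seed = seed,
                         per_class_counts = config$split$per_class_counts)
  tr_idx <- match(sp$train$id, ds$id); ex_idx <- match(sp$external$id, ds$id)

  # --- stage 4: CV model selection
  grids <- config$grids %||% default_grids()[config$algorithms]
  grid <- build_grid(blocks, config$algorithms, grids,
                     include_pairs = isTRUE(config$include_pairs), seed = seed)
  results <- lapply(grid, function(g) {
    blk <- combine_blocks(blocks[g$combo])
    run_repeated_cv(subset_block(blk, tr_idx), sp$train$label, g$spec,
                    folds = config$cv$folds %||% 5,
                    repeats = config$cv$repeats %||% 10,
                    seed = seed, smote = config$smote)
  })
  cv_tab <- cv_summary_table(results)
  cv_tab <- cv_tab[order(-cv_tab$mean_AUC, -cv_tab$mean_MCC), ]
  write_csv_artifact(cv_tab, file.path(output_dir, "cv_results.csv"), hash)
  top <- select_top(results, config$top_n %||% 5)

  # --- stage 5: external validation + consensus
  ext_rows <- list(); scores <- list(); top_models <- list()
  for (r in top) {
    combo_names <- strsplit(r$combo, "+", fixed = TRUE)[[1]]
    spec <- classifier_spec(r$algorithm, r$params, seed = seed)
    fpe <- fit_and_predict_external(
      subset_block(combine_blocks(blocks[combo_names]), tr_idx), sp$train$label,
      subset_block(combine_blocks(blocks[combo_names]), ex_idx), spec,
      external_labels = sp$external$label, smote = config$smote)
    scores[[model_label(r)]] <- fpe$predictions$score
    top_models[[model_label(r)]] <- fpe$model
    ext_rows[[length(ext_rows) + 1]] <- data.frame(
      model = r$algorithm, features = r$combo,
      t(format_metrics(fpe$metrics)), stringsAsFactors = FALSE)
  }
  if (length(scores) >= 2) {
    cons <- consensus_predict(scores)
    mcons <- classification_metrics(
      confusion_from_predictions(sp$external$label, cons$label))
    mcons$AUC <- auc_score(sp$external$label, cons$score)
    ext_rows[[length(ext_rows) + 1]] <- data.frame(
      model = "consensus", features = "/", t(format_metrics(mcons)),
      stringsAsFactors = FALSE)
  }
  ext_tab <- do.call(rbind, ext_rows)
  write_csv_artifact(ext_tab, file.path(output_dir, "external_validation.csv"), hash)

  # --- stage 6: applicability domain (feature space of the best model)
  best <- top[[1]]
  best_model <- top_models[[model_label(best)]]
  blk_best <- combine_blocks(blocks[strsplit(best$combo, "+", fixed = TRUE)[[1]]])
  Xtr_ad <- predict(best_model$preprocessor, subset_block(blk_best, tr_idx))$matrix
  Xex_ad <- predict(best_model$preprocessor, subset_block(blk_best, ex_idx))$matrix
  ad <- fit_ad(Xtr_ad, percentile = config$ad$percentile %||% 0.95,
               method = config$ad$method %||% "nn")
  cov_tr <- ad_coverage(ad, Xtr_ad, sp$train$label)
  cov_ex <- ad_coverage(ad, Xex_ad, sp$external$label)
  ad_tab <- data.frame(
    set = c("training", "external"),
    inside_P = c(cov_tr$per_class$inside[1], cov_ex$per_class$inside[1]),
    inside_N = c(cov_tr$per_class$inside[2], cov_ex$per_class$inside[2]),
    outside_P = c(cov_tr$per_class$outside[1], cov_ex$per_class$outside[1]),
    outside_N = c(cov_tr$per_class$outside[2], cov_ex$per_class$outside[2]),
    coverage_pct = c(cov_tr$coverage_pct, cov_ex$coverage_pct))
  write_csv_artifact(ad_tab, file.path(output_dir, "ad_coverage.csv"), hash)

  # --- stage 7: structural alerts
  frag_name <- config$alerts$block %||%
    names(blocks)[vapply(blocks, function(b) b$kind, "") == "binary"][1]
  alerts <- NULL
  if (!is.na(frag_name)) {
    scope_idx <- if (identical(config$alerts$scope, "train")) tr_idx
                 else seq_len(nrow(ds))
    alerts <- mine_alerts(subset_block(blocks[[frag_name]], scope_idx),
                          ds$label[scope_idx],
                          min_occurrences = config$alerts$min_occurrences %||% 7,
                          top_n = config$alerts$top_n)
    write_csv_artifact(as.data.frame(alerts), file.path(output_dir, "alerts.csv"), hash)
  }

  manifest <- list(config = config, seed = seed, config_hash = hash,
                   package_version = as.character(utils::packageVersion("ditpqsar")),
                   n_models_evaluated = length(results),
                   best_model = model_label(best))
  write_json_artifact(manifest, file.path(output_dir, "run_manifest.json"))
  invisible(list(summary = summ, cv = cv_tab, external = ext_tab, ad = ad_tab,
                 alerts = alerts, manifest = manifest, output_dir = output_dir))
}

write_csv_artifact <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}
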