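#' Labeled DITP molecule dataset
#'
#' Construct a labeled dataset of molecules for DITP (drug-induced immune
#' thrombocytopenia) toxicity modeling. Each record carries a unique id, a
#' SMILES string and a binary label (1 = DITP toxicant, 0 = non-toxicant).
#'
#' @param id character vector of unique, non-empty molecule identifiers.
#' @param smiles character vector of SMILES strings (may be `NA` for purely
#'   synthetic feature datasets when `validate_smiles = FALSE`).
#' @param label binary vector in `{0, 1}`.
#' @param validate_smiles if `TRUE` (default), every SMILES is parsed by the
#'   chemistry provider and unparseable rows raise an error naming them.
#' @return An object of class `ditp_dataset`: a data.frame with columns
#'   `id`, `smiles`, `label`.
#' @examples
#' ds <- ditp_dataset(c("a", "b"), c("CCO", "c1ccccc1"), c(1, 0))
#' class_proportions(ds)
#' @export
ditp_dataset <- function(id, smiles, label, validate_smiles = TRUE) {
  id <- as.character(id)
  if (any(!nzchar(id)) || anyNA(id)) stopf("molecule ids must be non-empty")
  if (anyDuplicated(id)) stopf("duplicate molecule id(s): %s",
                               paste(unique(id[duplicated(id)]), collapse = ", "))
  if (!all(label %in% c(0, 1))) stopf("labels must be 0 (non-toxicant) or 1 (toxicant)")
  if (length(smiles) != length(id) || length(label) != length(id))
    stopf("id, smiles and label must have equal length")
  if (validate_smiles) {
    parsed <- parse_molecules(as.character(smiles), id)
    if (any(!parsed$ok)) {
      bad <- which(!parsed$ok)
      stopf("unparseable SMILES at row(s) %s (id %s): %s",
            paste(bad, collapse = ", "), paste(id[bad], collapse = ", "),
            paste(unique(trimws(parsed$errors[bad])), collapse = "; "))
    }
  }
  ds <- data.frame(id = id, smiles = as.character(smiles),
                   label = as.integer(label), stringsAsFactors = FALSE)
  class(ds) <- c("ditp_dataset", "data.frame")
  ds
}

#' @export
print.ditp_dataset <- function(x, ...) {
  p <- class_proportions(x)
  cat(sprintf("<ditp_dataset> %d molecules: %d toxicants, %d non-toxicants (P1 = %.3f)\n",
              nrow(x), sum(x$label == 1), sum(x$label == 0), p[["1"]]))
  invisible(x)
}

#' Class proportions of a labeled dataset
#'
#' The per-class fractions used as the prior \eqn{P_k} in the entropy of the
#' class variable (see [information_gain()]).
#'
#' @param ds a [ditp_dataset()].
#' @return named numeric vector `c("0" = ..., "1" = ...)` summing to 1.
#' @export
class_proportions <- function(ds) {
  stopifnot(inherits(ds, "ditp_dataset"), nrow(ds) > 0)
  c("0" = mean(ds$label == 0), "1" = mean(ds$label == 1))
}

#' Read a labeled molecule table
#'
#' Reads a CSV (header row) or SMI (whitespace-separated `SMILES id [label]`)
#' file into a [ditp_dataset()]. Rows whose SMILES the chemistry provider
#' rejects are dropped and reported with their row numbers.
#'
#' @param path file path.
#' @param format `"csv"` or `"smi"`.
#' @param column_map named list mapping the roles `id`, `smiles`, `label` to
#'   column names (CSV only; default `list(id="id", smiles="smiles",
#'   label="label")`). An optional `label_values` entry maps textual labels to
#'   0/1, e.g. `list(toxicant = 1, `non-toxicant` = 0)`; without it labels
#'   must already be 0/1.
#' @param sep CSV delimiter (default `","`).
#' @param drop_invalid if `TRUE` (default) unparseable-SMILES rows are removed
#'   with a warning naming them; if `FALSE` they raise an error.
#' @return a [ditp_dataset()] with attribute `"rejected_rows"` (integer row
#'   numbers of dropped records, possibly empty).
#' @export
read_dataset <- function(path, format = c("csv", "smi"),
                         column_map = list(), sep = ",",
                         drop_invalid = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "csv") {
    cmap <- utils::modifyList(list(id = "id", smiles = "smiles", label = "label"),
                              column_map)
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "", quote = "\"")
    for (role in c("id", "smiles", "label"))
      if (!cmap[[role]] %in% names(tab))
        stopf("mapped column '%s' (role %s) missing from %s", cmap[[role]], role, path)
    id <- as.character(tab[[cmap$id]])
    smiles <- as.character(tab[[cmap$smiles]])
    label <- tab[[cmap$label]]
    if (!is.null(cmap$label_values)) {
      lv <- cmap$label_values
      if (!all(as.character(label) %in% names(lv)))
        stopf("label value(s) not covered by column_map$label_values: %s",
              paste(setdiff(unique(as.character(label)), names(lv)), collapse = ", "))
      label <- unlist(lv[as.character(label)], use.names = FALSE)
    }
    if (!all(label %in% c(0, 1)))
      stopf("non-binary label value(s): %s (supply column_map$label_values for textual labels)",
            paste(setdiff(unique(label), c(0, 1)), collapse = ", "))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    smiles <- vapply(parts, `[[`, "", 1L)
    id <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
    if (any(!nzchar(id))) stopf("SMI rows without an id field: %s",
                                paste(which(!nzchar(id)), collapse = ", "))
    label <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else NA_character_, "")
    if (anyNA(label)) stopf("SMI rows without a label field: %s",
                            paste(which(is.na(label)), collapse = ", "))
    label <- suppressWarnings(as.numeric(label))
    if (anyNA(label) || !all(label %in% c(0, 1))) stopf("non-binary label in SMI file")
  }
  if (anyDuplicated(id))
    stopf("duplicate molecule id(s): %s", paste(unique(id[duplicated(id)]), collapse = ", "))
  parsed <- parse_molecules(smiles, id)
  rejected <- which(!parsed$ok)
  if (length(rejected)) {
    msg <- sprintf("rejected %d row(s) with unparseable SMILES: row %s (id %s)",
                   length(rejected), paste(rejected, collapse = ", "),
                   paste(id[rejected], collapse = ", "))
    if (!drop_invalid) stopf("%s", msg)
    warnf("%s", msg)
    keep <- setdiff(seq_along(id), rejected)
    id <- id[keep]; smiles <- smiles[keep]; label <- label[keep]
  }
  ds <- ditp_dataset(id, smiles, label, validate_smiles = FALSE)
  attr(ds, "rejected_rows") <- rejected
  ds
}

#' Stratified train/external split
#'
#' Randomly partitions a dataset into a training and an external validation
#' set, stratified by class. Per-class training counts follow the
#' largest-remainder rule on `train_fraction * n_class`: each class first
#' receives `floor(train_fraction * n_class)` members and the remaining seats
#' (up to the rounded overall training size) go to the classes with the
#' largest fractional remainders. Explicit `per_class_counts` override the
#' rule, e.g. to reproduce a published split exactly.
#'
#' @param ds a [ditp_dataset()].
#' @param train_fraction fraction in (0, 1) (default 0.8, the study's 8:2 ratio).
#' @param seed integer seed; identical seeds give identical splits.
#' @param per_class_counts optional named vector/list `c(pos = , neg = )` of
#'   exact per-class training counts.
#' @return `list(train = , external = )` of two [ditp_dataset()]s.
#' @examples
#' ds <- ditp_dataset(sprintf("m%d", 1:10), rep("CCO", 10),
#'                    rep(c(1, 0), 5), validate_smiles = FALSE)
#' sp <- stratified_split(ds, 0.8, seed = 1)
#' nrow(sp$train)  # 8
#' @export
stratified_split <- function(ds, train_fraction = 0.8, seed = 1,
                             per_class_counts = NULL) {
  stopifnot(inherits(ds, "ditp_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1))
    stopf("train_fraction must be in (0, 1)")
  n_pos <- sum(ds$label == 1); n_neg <- sum(ds$label == 0)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present to split")
  if (!is.null(per_class_counts)) {
    take_pos <- as.integer(per_class_counts[["pos"]])
    take_neg <- as.integer(per_class_counts[["neg"]])
    if (take_pos > n_pos || take_neg > n_neg)
      stopf("per_class_counts exceed per-class totals")
  } else {
    quota <- train_fraction * c(pos = n_pos, neg = n_neg)
    base <- floor(quota)
    seats <- round_half_up(train_fraction * (n_pos + n_neg)) - sum(base)
    take <- base
    if (seats > 0) {
      ord <- order(quota - base, c(n_pos, n_neg), decreasing = TRUE)
      take[ord[seq_len(seats)]] <- take[ord[seq_len(seats)]] + 1
    }
    take_pos <- take[["pos"]]; take_neg <- take[["neg"]]
  }
  if (take_pos < 1 || take_neg < 1 || take_pos >= n_pos + 1 || take_neg >= n_neg + 1)
    stopf("split would leave a class empty in one partition")
  if (take_pos == n_pos && take_neg == n_neg)
    stopf("split would leave the external set empty")
  idx_pos <- which(ds$label == 1); idx_neg <- which(ds$label == 0)
  train_idx <- with_seed(seed, {
    c(sample(idx_pos, take_pos), sample(idx_neg, take_neg))
  })
  train_idx <- sort(train_idx)
  subset_ds <- function(i) {
    out <- ditp_dataset(ds$id[i], ds$smiles[i], ds$label[i], validate_smiles = FALSE)
    out
  }
  list(train = subset_ds(train_idx),
       external = subset_ds(setdiff(seq_len(nrow(ds)), train_idx)))
}

#' Summarize a labeled dataset
#'
#' Per-class counts plus per-molecule basic physicochemical properties
#' (via [basic_properties()]) for downstream plotting or export.
#'
#' @param ds a [ditp_dataset()].
#' @param properties compute per-molecule properties (requires parseable
#'   SMILES); set `FALSE` for synthetic id/label stubs.
#' @return `list(n, counts, proportions, single_class, properties)`.
#' @export
dataset_summary <- function(ds, properties = TRUE) {
  stopifnot(inherits(ds, "ditp_dataset"))
  if (nrow(ds) == 0) stopf("empty dataset")
  counts <- c(pos = sum(ds$label == 1), neg = sum(ds$label == 0))
  single <- any(counts == 0)
  if (single) warnf("dataset contains a single class")
  props <- if (properties) basic_properties(ds) else NULL
  list(n = nrow(ds), counts = counts,
       proportions = counts / nrow(ds),
       single_class = single, properties = props)
}
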